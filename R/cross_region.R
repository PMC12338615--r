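#' Combine two regions' pseudobulk matrices for within-donor comparison
#'
#' Restricts both pseudobulks to their gene intersection, concatenates the
#' columns, recomputes log2(CPM+1) on the combined matrix, and builds the
#' `Tissue`, `Donor`, `Layer` metadata plus the derived `Layer_Tissue`
#' factor used by the mixed model. At least one donor must be shared between
#' regions, otherwise the donor random effect is undefined.
#'
#' @param pb_a,pb_b [pseudobulk()] objects for the two regions.
#' @param tissues length-2 character, region names.
#' @return a `combined_pseudobulk`: `counts`, `logexpr`, `meta` with
#'   Tissue/Donor/Layer/Layer_Tissue.
#' @export
combine_pseudobulks <- function(pb_a, pb_b, tissues = c("A", "B")) {
  shared <- intersect(rownames(pb_a$counts), rownames(pb_b$counts))
  if (!length(shared)) stop("the two pseudobulks share no genes")
  if (!length(intersect(pb_a$meta$donor, pb_b$meta$donor))) {
    stop("no shared donors; the donor random effect is undefined")
  }
  counts <- cbind(pb_a$counts[shared, , drop = FALSE],
                  pb_b$counts[shared, , drop = FALSE])
  meta <- data.frame(
    Tissue = rep(tissues, c(ncol(pb_a$counts), ncol(pb_b$counts))),
    Donor = c(pb_a$meta$donor, pb_b$meta$donor),
    Layer = c(pb_a$meta$group, pb_b$meta$group),
    stringsAsFactors = FALSE
  )
  meta$Layer_Tissue <- paste(meta$Layer, meta$Tissue, sep = "_")
  colnames(counts) <- paste(meta$Layer_Tissue, meta$Donor,
                            seq_len(ncol(counts)), sep = ".")
  rownames(meta) <- colnames(counts)
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  structure(
    list(counts = counts, logexpr = log2(cpm + 1), meta = meta),
    class = "combined_pseudobulk"
  )
}

#' Per-gene random-intercept mixed-model contrast between two layer-tissue
#' levels
#'
#' Fits, per gene, `logexpr ~ Layer_Tissue` fixed effects with a donor
#' random intercept by REML, profiling the variance ratio (donor variance
#' over residual variance) by one-dimensional minimization on the log scale
#' and comparing against the ratio-zero (OLS) boundary. The requested
#' contrast is Wald-tested against the normal reference, and the p-value is
#' also returned as a signed z-score carrying the sign of the estimate (the
#' scale the DEG decision rule operates on). Genes where the REML profile
#' fails fall back to the OLS fit with a flag.
#'
#' @param cpb a [combine_pseudobulks()] object.
#' @param level_a,level_b `Layer_Tissue` levels to contrast
#'   (logFC = level_a - level_b).
#' @param genes optional subset of genes.
#' @param lambda fix the variance ratio instead of profiling it (0 gives the
#'   ordinary least-squares fit); `NULL` estimates it per gene by REML.
#' @return data.frame (gene, logFC, z, p, lambda, ols_fallback).
#' @export
mixed_model_contrast <- function(cpb, level_a, level_b, genes = NULL,
                                 lambda = NULL) {
  meta <- cpb$meta
  lt <- factor(meta$Layer_Tissue)
  if (!level_a %in% levels(lt) || !level_b %in% levels(lt)) {
    stop("both Layer_Tissue levels must be present")
  }
  Y <- cpb$logexpr
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  X <- stats::model.matrix(~ 0 + lt)
  colnames(X) <- levels(lt)
  Z <- stats::model.matrix(~ 0 + factor(meta$Donor))
  n <- nrow(X)
  p <- qr(X)$rank
  if (n - p < 1) stop("no residual degrees of freedom")

  # one eigendecomposition of ZZ' serves every gene and every lambda:
  # V = I + lambda ZZ' has eigenvectors U and eigenvalues 1 + lambda * d
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  Xt <- crossprod(U, X)
  Yt <- Y %*% U           # genes x n, rotated
  cvec <- as.numeric(colnames(X) == level_a) -
    as.numeric(colnames(X) == level_b)

  reml_fit <- function(y, lambda) {
    w <- 1 / (1 + lambda * d)
    XtW <- Xt * w
    A <- crossprod(Xt, XtW)
    Ai <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
    if (is.null(Ai)) return(NULL)
    beta <- Ai %*% crossprod(XtW, y)
    r <- y - Xt %*% beta
    rss <- sum(w * r^2)
    sigma2 <- rss / (n - p)
    crit <- (n - p) * log(rss) - sum(log(w)) +
      determinant(A, logarithm = TRUE)$modulus[1]
    list(crit = crit, beta = beta, sigma2 = sigma2, Ai = Ai)
  }

  fit_gene <- function(y) {
    fallback <- FALSE
    if (!is.null(lambda)) {
      lam <- lambda
      best <- reml_fit(y, lam)
    } else {
      obj <- function(ll) {
        f <- reml_fit(y, exp(ll))
        if (is.null(f)) Inf else f$crit
      }
      opt <- tryCatch(
        stats::optimize(obj, interval = c(-10, 10), tol = 1e-8),
        error = function(e) NULL
      )
      f0 <- reml_fit(y, 0)
      if (is.null(opt) || !is.finite(opt$objective)) {
        best <- f0
        lam <- 0
        fallback <- TRUE
      } else if (f0$crit <= opt$objective) {
        best <- f0
        lam <- 0
      } else {
        lam <- exp(opt$minimum)
        best <- reml_fit(y, lam)
      }
    }
    est <- sum(cvec * best$beta)
    se <- sqrt(best$sigma2 * drop(t(cvec) %*% best$Ai %*% cvec))
    zw <- if (se > 0) est / se else 0
    pv <- 2 * stats::pnorm(-abs(zw))
    zs <- sign(est) * stats::qnorm(1 - pv / 2)
    if (est == 0) zs <- 0
    c(est, zs, pv, lam, fallback)
  }

  out <- t(apply(Yt, 1, fit_gene))
  data.frame(
    gene = rownames(Y), logFC = out[, 1], z = out[, 2], p = out[, 3],
    lambda = out[, 4], ols_fallback = out[, 5] > 0, row.names = NULL
  )
}

#' Count differentially expressed genes under the joint z / logFC rule
#'
#' A gene counts as significantly DE when `|z| > z_cut` and
#' `|logFC| > lfc_cut`, both strict inequalities.
#'
#' @param contrast_results a [mixed_model_contrast()] table.
#' @param z_cut,lfc_cut the decision thresholds.
#' @return integer DEG count.
#' @export
count_degs <- function(contrast_results, z_cut = 1.645, lfc_cut = 1.5) {
  sum(abs(contrast_results$z) > z_cut &
        abs(contrast_results$logFC) > lfc_cut)
}

#' DEG count matrix over all cross-region domain pairs, raw and row-scaled
#'
#' Runs [mixed_model_contrast()] for every (region-A domain, region-B
#' domain) combination, counts DEGs with [count_degs()], and scales each row
#' by that A-domain's total DEGs across all its comparisons (rows sum to 1
#' when the total is positive).
#'
#' @param cpb a [combine_pseudobulks()] object.
#' @param layers_a,layers_b domain labels per region (defaults: all observed).
#' @param tissues the two tissue codes used in `Layer_Tissue`.
#' @param z_cut,lfc_cut passed to [count_degs()].
#' @return list: `raw` and `scaled` (A domains x B domains), `contrasts`
#'   (list of per-pair tables).
#' @export
deg_count_matrix <- function(cpb, layers_a = NULL, layers_b = NULL,
                             tissues = c("A", "B"), z_cut = 1.645,
                             lfc_cut = 1.5) {
  meta <- cpb$meta
  if (is.null(layers_a)) layers_a <- sort(unique(meta$Layer[meta$Tissue == tissues[1]]))
  if (is.null(layers_b)) layers_b <- sort(unique(meta$Layer[meta$Tissue == tissues[2]]))
  raw <- matrix(0L, length(layers_a), length(layers_b),
                dimnames = list(layers_a, layers_b))
  contrasts <- list()
  for (la in layers_a) {
    for (lb in layers_b) {
      res <- mixed_model_contrast(cpb, paste(la, tissues[1], sep = "_"),
                                  paste(lb, tissues[2], sep = "_"))
      raw[la, lb] <- count_degs(res, z_cut, lfc_cut)
      contrasts[[paste(la, lb, sep = ".")]] <- res
    }
  }
  totals <- rowSums(raw)
  scaled <- raw / ifelse(totals > 0, totals, 1)
  scaled[totals == 0, ] <- NA_real_
  list(raw = raw, scaled = scaled, contrasts = contrasts)
}

#' Classify cross-region enrichment concordance of log fold-changes
#'
#' Joins two regions' one-vs-rest logFC vectors for a chosen domain in each
#' region over their shared genes and classifies every gene: A-enriched
#' (`logFC_A > cut`, `logFC_B <= cut`), B-enriched (symmetric), both, or
#' neither; the Pearson correlation is computed over all shared genes.
#'
#' @param stats_a,stats_b enrichment DE tables for the two regions.
#' @param group_a,group_b the domain compared in each region.
#' @param enrich_cut logFC threshold for calling enrichment.
#' @return list: `table` (gene, logFC_A, logFC_B, category) and `r`.
#' @export
logfc_concordance <- function(stats_a, stats_b, group_a, group_b,
                              enrich_cut = 1.25) {
  a <- stats_a[stats_a$group == group_a, c("gene", "logFC")]
  b <- stats_b[stats_b$group == group_b, c("gene", "logFC")]
  m <- merge(a, b, by = "gene", suffixes = c("_A", "_B"))
  if (!nrow(m)) stop("no shared genes between the two stats tables")
  above_a <- m$logFC_A > enrich_cut
  above_b <- m$logFC_B > enrich_cut
  m$category <- ifelse(above_a & above_b, "both",
                       ifelse(above_a, "A_enriched",
                              ifelse(above_b, "B_enriched", "neither")))
  list(table = m, r = stats::cor(m$logFC_A, m$logFC_B))
}
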