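#' Pseudobulk a count assay by group and sample
#'
#' Sums UMI counts over all observations sharing a (group, sample) pair, the
#' standard trick that turns sparse spot/nucleus data into bulk-like columns
#' amenable to linear-model DE machinery. Columns with fewer than `min_obs`
#' member observations are dropped and reported. Before modeling, genes are
#' prefiltered by a deterministic expression rule: CPM >= `min_cpm` in at
#' least as many columns as the smallest group has.
#'
#' @param assay a `count_assay` whose `obs_meta` contains `group_key` and
#'   `sample_key` columns (and optionally `donor`).
#' @param group_key,sample_key names of the metadata columns.
#' @param min_obs minimum observations per retained column.
#' @param min_cpm CPM threshold of the gene prefilter (set `NULL` to skip).
#' @return a `pseudobulk` object: `counts` (genes x columns), `meta`
#'   (group, sample, donor, n_obs), and `logexpr` = log2(CPM + 1).
#' @export
pseudobulk <- function(assay, group_key = "group", sample_key = "sample",
                       min_obs = 10, min_cpm = 1) {
  meta <- assay$obs_meta
  if (!group_key %in% names(meta) || !sample_key %in% names(meta)) {
    stop("obs_meta must contain the group and sample columns")
  }
  grp <- as.character(meta[[group_key]])
  smp <- as.character(meta[[sample_key]])
  key <- paste(grp, smp, sep = "\r")
  f <- factor(key)
  ind <- Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f))
  )
  counts <- assay$counts %*% ind
  parts <- do.call(rbind, strsplit(levels(f), "\r", fixed = TRUE))
  n_obs <- as.integer(table(f))
  donor <- if ("donor" %in% names(meta)) {
    vapply(levels(f), function(l) meta$donor[key == l][1], character(1))
  } else {
    parts[, 2]
  }
  cmeta <- data.frame(group = parts[, 1], sample = parts[, 2],
                      donor = unname(donor), n_obs = n_obs,
                      stringsAsFactors = FALSE)
  keep <- cmeta$n_obs >= min_obs
  dropped <- cmeta[!keep, , drop = FALSE]
  counts <- as.matrix(counts[, keep, drop = FALSE])
  cmeta <- cmeta[keep, , drop = FALSE]
  if (length(unique(cmeta$group)) < 2) {
    stop("fewer than 2 groups survive pseudobulking")
  }
  colnames(counts) <- paste(cmeta$group, cmeta$sample, sep = "_")
  rownames(cmeta) <- colnames(counts)
  rownames(counts) <- assay$gene_ids

  cpm <- t(t(counts) / colSums(counts)) * 1e6
  if (!is.null(min_cpm)) {
    min_group <- min(table(cmeta$group))
    gkeep <- rowSums(cpm >= min_cpm) >= min_group
    counts <- counts[gkeep, , drop = FALSE]
    cpm <- cpm[gkeep, , drop = FALSE]
  }
  structure(
    list(counts = counts, meta = cmeta, logexpr = log2(cpm + 1),
         dropped_columns = dropped),
    class = "pseudobulk"
  )
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d columns (%d groups, %d samples)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$group)), length(unique(x$meta$sample))))
  invisible(x)
}

# ---- empirical-Bayes variance moderation -----------------------------------

# Newton inversion of the trigamma function (tol 1e-8)
trigamma_inverse <- function(z) {
  if (z > trigamma(1e-6)) return(1e-6)
  x <- 0.5 + 1 / z
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / z) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

# Moment-matching estimate of the prior df d0 and prior variance s0^2 of the
# scaled-F model for per-gene variances (the standard moderated-t
# construction). d0 is capped to avoid numeric overflow.
estimate_variance_prior <- function(s2, df, d0_cap = 500) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
  } else {
    d0 <- Inf
  }
  d0 <- min(d0, d0_cap)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(prior_df = d0, prior_var = s0_sq)
}

# Per-gene least squares on a shared design with moderated t for one
# coefficient. Y: genes x n; X: n x p; coef: column index tested.
moderated_fit <- function(Y, X, coef, prior_df = NULL) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  p <- ncol(X)
  df_res <- n - p
  if (df_res < 1) stop("no residual degrees of freedom")
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% XtXinv
  res <- Y - B %*% t(X)
  s2 <- rowSums(res^2) / df_res
  if (is.null(prior_df)) {
    pri <- estimate_variance_prior(s2, df_res)
  } else {
    pri <- list(prior_df = prior_df,
                prior_var = if (prior_df > 0) stats::median(s2) else NA_real_)
  }
  d0 <- pri$prior_df
  s2_post <- if (d0 > 0) {
    (d0 * pri$prior_var + df_res * s2) / (d0 + df_res)
  } else {
    s2
  }
  df_total <- df_res + d0
  v <- XtXinv[coef, coef]
  tstat <- B[, coef] / sqrt(s2_post * v)
  pval <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  list(logFC = B[, coef], t = tstat, p = pval,
       df_res = df_res, prior_df = d0, prior_var = pri$prior_var)
}

build_design <- function(meta, indicator, covariates) {
  df <- data.frame(.ind = indicator)
  for (cv in covariates) {
    if (!cv %in% names(meta)) stop("unknown covariate: ", cv)
    v <- meta[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  stats::model.matrix(~ ., data = df)
}

#' One-vs-rest enrichment model with moderated t-statistics
#'
#' For each group, fits per-gene least squares of log2(CPM+1) on a
#' member-vs-rest indicator plus covariate fixed effects; per-gene residual
#' variances are shrunk by empirical Bayes (moment-matched prior df and
#' variance), giving a moderated t per gene and group, the molecular
#' fingerprint used for spatial registration. FDR is Benjamini-Hochberg per
#' group.
#'
#' @param pb a [pseudobulk()] object.
#' @param covariates metadata columns used as fixed-effect covariates
#'   (default donor; set `character()` for none).
#' @param prior_df force the prior df (0 gives the ordinary per-gene OLS t);
#'   `NULL` estimates it.
#' @return data.frame (gene, group, logFC, t, p, fdr) with per-group model
#'   metadata in attribute `model_info`.
#' @export
enrichment_model <- function(pb, covariates = "donor", prior_df = NULL) {
  groups <- sort(unique(pb$meta$group))
  out <- vector("list", length(groups))
  info <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    X <- build_design(pb$meta, pb$meta$group == g, covariates)
    fit <- moderated_fit(pb$logexpr, X, coef = 2, prior_df = prior_df)
    out[[i]] <- data.frame(
      gene = rownames(pb$logexpr), group = g, logFC = fit$logFC,
      t = fit$t, p = fit$p, fdr = stats::p.adjust(fit$p, "BH"),
      row.names = NULL
    )
    info[[i]] <- data.frame(group = g, df_res = fit$df_res,
                            prior_df = fit$prior_df,
                            prior_var = fit$prior_var)
  }
  res <- do.call(rbind, out)
  attr(res, "model_info") <- do.call(rbind, info)
  res
}

#' Pairwise differential expression between two groups
#'
#' Same moderated-t machinery as [enrichment_model()], restricted to the two
#' groups' columns; sign convention `logFC = mean(group_a) - mean(group_b)`.
#'
#' @param pb a [pseudobulk()] object.
#' @param group_a,group_b the two group labels.
#' @param covariates fixed-effect covariate columns (default none).
#' @param prior_df as in [enrichment_model()].
#' @return data.frame (gene, group, logFC, t, p, fdr); `group` is
#'   `"a_vs_b"`.
#' @export
pairwise_model <- function(pb, group_a, group_b, covariates = character(),
                           prior_df = NULL) {
  sel <- pb$meta$group %in% c(group_a, group_b)
  if (!any(pb$meta$group == group_a) || !any(pb$meta$group == group_b)) {
    stop("both groups must be present in the pseudobulk")
  }
  meta <- pb$meta[sel, , drop = FALSE]
  Y <- pb$logexpr[, sel, drop = FALSE]
  X <- build_design(meta, meta$group == group_a, covariates)
  fit <- moderated_fit(Y, X, coef = 2, prior_df = prior_df)
  res <- data.frame(
    gene = rownames(Y), group = paste(group_a, "vs", group_b, sep = "_"),
    logFC = fit$logFC, t = fit$t, p = fit$p,
    fdr = stats::p.adjust(fit$p, "BH"), row.names = NULL
  )
  attr(res, "model_info") <- data.frame(
    group = unique(res$group), df_res = fit$df_res,
    prior_df = fit$prior_df, prior_var = fit$prior_var
  )
  res
}

#' Flag significant genes by joint FDR and fold-change cut-offs
#'
#' Significance requires both `fdr < alpha` and `|logFC| > lfc_cut`.
#'
#' @param stats a DE table from [enrichment_model()] or [pairwise_model()].
#' @param lfc_cut absolute log2 fold-change cut-off.
#' @param alpha FDR cut-off.
#' @return the table with a logical `significant` column.
#' @export
significant_genes <- function(stats, lfc_cut = 1.5, alpha = 0.05) {
  stats$significant <- stats$fdr < alpha & abs(stats$logFC) > lfc_cut
  stats
}

#' Top markers per group ranked by t-statistic
#'
#' @param stats a DE table.
#' @param n markers per group (full ranking with a warning if larger than
#'   the gene count).
#' @return data.frame of the top rows per group, ranked by t descending.
#' @export
top_markers <- function(stats, n = 50) {
  do.call(rbind, lapply(split(stats, stats$group), function(s) {
    if (n > nrow(s)) {
      warning("n exceeds the gene count; returning the full ranking")
    }
    s <- s[order(-s$t), , drop = FALSE]
    utils::head(s, n)
  }))
}
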