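#' Non-negative matrix factorization by HALS
#'
#' Minimizes the Frobenius loss `||X - W H||_F^2` over non-negative `W`
#' (genes x k loadings) and `H` (k x observations weights) by hierarchical
#' alternating least squares: each factor column/row is updated in closed
#' form with projection to the non-negative orthant, which makes the loss
#' non-increasing across sweeps. Initialization is from seeded uniform draws
#' scaled to the data mean; on convergence the columns of `W` are normalized
#' to unit L2 norm with the scale moved into `H`.
#'
#' @param X non-negative matrix (genes x observations), typically
#'   log-normalized expression; a `lognorm_matrix` is accepted.
#' @param k rank (must be < min(dim(X))).
#' @param seed integer seed for the initialization.
#' @param max_iter maximum sweeps.
#' @param tol relative loss-change stopping tolerance.
#' @return an `nmf_model`: `W`, `H`, `k`, `objective_trace`, `seed`.
#' @export
nmf_fit <- function(X, k, seed = 1, max_iter = 500, tol = 1e-6) {
  if (inherits(X, "lognorm_matrix")) X <- X$values
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  if (k >= min(dim(X))) stop("k must be smaller than both dimensions of X")
  set.seed(seed)
  G <- nrow(X)
  N <- ncol(X)
  scale <- sqrt(2 * mean(X) / k)
  W <- matrix(stats::runif(G * k), G, k) * scale
  H <- matrix(stats::runif(k * N), k, N) * scale
  norm_x2 <- sum(X^2)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    upd <- hals_sweep(X, W, H)
    W <- upd$W
    H <- upd$H
    loss <- norm_x2 - 2 * sum(upd$WtX * H) + sum(upd$WtW * tcrossprod(H))
    trace <- c(trace, loss)
    if (is.finite(prev) && (prev - loss) < tol * max(prev, 1e-12)) break
    prev <- loss
  }
  nrm <- sqrt(colSums(W^2))
  pos <- nrm > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2, nrm[pos], `/`)
  H[pos, ] <- H[pos, , drop = FALSE] * nrm[pos]
  pat <- sprintf("P%02d", seq_len(k))
  dimnames(W) <- list(rownames(X), pat)
  dimnames(H) <- list(pat, colnames(X))
  structure(
    list(W = W, H = H, k = k, objective_trace = trace, seed = seed),
    class = "nmf_model"
  )
}

# one full HALS sweep (W columns then H rows); returns the cross-products
# current at the time of the H update so the caller can form the loss
hals_sweep <- function(X, W, H) {
  HHt <- tcrossprod(H)
  XHt <- as.matrix(X %*% t(H))
  for (j in seq_len(nrow(H))) {
    d <- HHt[j, j]
    if (d < 1e-12) next
    W[, j] <- pmax(0, W[, j] + (XHt[, j] - W %*% HHt[, j]) / d)
  }
  WtW <- crossprod(W)
  WtX <- as.matrix(crossprod(W, X))
  for (j in seq_len(nrow(H))) {
    d <- WtW[j, j]
    if (d < 1e-12) next
    H[j, ] <- pmax(0, H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / d)
  }
  list(W = W, H = H, WtW = WtW, WtX = WtX)
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("nmf_model: k = %d, %d genes x %d observations, final loss %.4g (%d sweeps)\n",
              x$k, nrow(x$W), ncol(x$H), utils::tail(x$objective_trace, 1),
              length(x$objective_trace)))
  invisible(x)
}

#' Select the NMF rank by speckled cross-validation
#'
#' Holds out a seeded random fraction of matrix entries, fits each candidate
#' rank on the observed entries (held-out entries are imputed by the current
#' reconstruction each sweep, the standard EM-style treatment), and scores
#' the mean squared error on the held-out entries, averaged over replicates.
#' The selected rank minimizes the mean held-out error; ties go to the
#' smaller rank.
#'
#' @param X non-negative matrix.
#' @param ranks candidate ranks (sorted ascending internally).
#' @param mask_fraction fraction of entries held out per replicate.
#' @param n_reps replicates (fresh mask and initialization each).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param max_iter,tol passed to the masked fits.
#' @return list with `per_rank` (rank, mean and per-rep held-out MSE) and
#'   `selected`.
#' @export
cross_validate_rank <- function(X, ranks, mask_fraction = 0.05, n_reps = 3,
                                seed = 1, max_iter = 100, tol = 1e-5) {
  if (inherits(X, "lognorm_matrix")) X <- X$values
  X <- as.matrix(X)
  if (!length(ranks)) stop("ranks must be nonempty")
  ranks <- sort(unique(ranks))
  mse <- matrix(NA_real_, length(ranks), n_reps,
                dimnames = list(paste0("k", ranks), paste0("rep", seq_len(n_reps))))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    mask <- draw_speckle_mask(dim(X), mask_fraction)
    for (i in seq_along(ranks)) {
      mse[i, r] <- masked_nmf_mse(X, ranks[i], mask, seed = seed + r,
                                  max_iter = max_iter, tol = tol)
    }
  }
  mean_mse <- rowMeans(mse)
  per_rank <- data.frame(rank = ranks, mean_mse = mean_mse, mse,
                         row.names = NULL)
  list(per_rank = per_rank, selected = ranks[which.min(mean_mse)])
}

# linear-index mask leaving at least one observed entry per row and column
draw_speckle_mask <- function(dims, fraction, max_tries = 10) {
  n_mask <- max(1L, round(fraction * prod(dims)))
  for (try in seq_len(max_tries)) {
    mask <- sample.int(prod(dims), n_mask)
    ri <- (mask - 1L) %% dims[1] + 1L
    ci <- (mask - 1L) %/% dims[1] + 1L
    row_masked <- tabulate(ri, dims[1])
    col_masked <- tabulate(ci, dims[2])
    if (all(row_masked < dims[2]) && all(col_masked < dims[1])) return(mask)
  }
  stop("mask repeatedly removed an entire row or column")
}

masked_nmf_mse <- function(X, k, mask, seed, max_iter, tol) {
  mi <- (mask - 1L) %% nrow(X) + 1L
  mj <- (mask - 1L) %/% nrow(X) + 1L
  held <- X[mask]
  Xi <- X
  Xi[mask] <- mean(X[-mask])
  set.seed(seed)
  scale <- sqrt(2 * mean(Xi) / k)
  W <- matrix(stats::runif(nrow(X) * k), ncol = k) * scale
  H <- matrix(stats::runif(k * ncol(X)), nrow = k) * scale
  prev <- Inf
  for (it in seq_len(max_iter)) {
    upd <- hals_sweep(Xi, W, H)
    W <- upd$W
    H <- upd$H
    wh <- rowSums(W[mi, , drop = FALSE] * t(H)[mj, , drop = FALSE])
    Xi[mask] <- wh
    loss <- sum((X[-mask] - (W %*% H)[-mask])^2)
    if (is.finite(prev) && (prev - loss) < tol * max(prev, 1e-12)) break
    prev <- loss
  }
  wh <- rowSums(W[mi, , drop = FALSE] * t(H)[mj, , drop = FALSE])
  mean((held - wh)^2)
}

#' Annotate NMF patterns with cell types
#'
#' Aggregates pattern weights by cell type (mean weight per pattern and
#' type); for each cell type the top pattern is the non-technical pattern
#' with the highest mean weight in that type, ties broken by the pattern's
#' specificity ratio (top mean over second mean across types) then by lower
#' pattern index. The top 10 loading genes are recorded per pattern.
#'
#' @param model an [nmf_fit()] model.
#' @param cell_labels one label per observation (column of `H`).
#' @param technical optional logical per pattern (from
#'   [technical_filter()]); technical patterns are excluded from top-pattern
#'   assignment.
#' @param n_top_genes marker genes recorded per pattern.
#' @return list: `mean_weights` (patterns x types), `top_pattern` (named by
#'   type), `top_genes` (list per pattern), `technical`.
#' @export
annotate_patterns <- function(model, cell_labels, technical = NULL,
                              n_top_genes = 10) {
  H <- model$H
  stopifnot(length(cell_labels) == ncol(H))
  f <- factor(cell_labels)
  mean_w <- t(apply(H, 1, function(h) tapply(h, f, mean)))
  colnames(mean_w) <- levels(f)
  if (is.null(technical)) technical <- rep(FALSE, nrow(H))
  spec_ratio <- apply(mean_w, 1, function(v) {
    s <- sort(v, decreasing = TRUE)
    if (length(s) < 2 || s[2] == 0) Inf else s[1] / s[2]
  })
  cand <- which(!technical)
  top_pattern <- vapply(colnames(mean_w), function(ct) {
    sc <- mean_w[cand, ct]
    pick <- cand[order(-sc, -spec_ratio[cand], cand)[1]]
    rownames(H)[pick]
  }, character(1))
  top_genes <- lapply(seq_len(ncol(model$W)), function(j) {
    rownames(model$W)[order(-model$W[, j])[seq_len(min(n_top_genes, nrow(model$W)))]]
  })
  names(top_genes) <- colnames(model$W)
  list(mean_weights = mean_w, top_pattern = top_pattern,
       top_genes = top_genes, technical = technical)
}

#' Flag technical NMF patterns by covariate correlation
#'
#' Computes the Pearson correlation of every pattern's weights with each
#' covariate: continuous covariates as given, categorical covariates as one
#' 0/1 dummy per level. A pattern is technical when its maximum absolute
#' correlation reaches `threshold`. Zero-variance patterns have undefined
#' correlations, treated as 0.
#'
#' @param model an [nmf_fit()] model.
#' @param covariates data.frame, one row per observation (e.g. mito percent,
#'   total and detected UMIs, donor, sex).
#' @param threshold absolute-correlation cutoff.
#' @return list: `technical` (logical per pattern), `cor` (patterns x
#'   covariate columns).
#' @export
technical_filter <- function(model, covariates, threshold = 0.5) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == ncol(model$H))
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      for (lv in unique(as.character(v))) {
        cols[[paste(nm, lv, sep = "_")]] <- as.numeric(v == lv)
      }
    }
  }
  cm <- do.call(cbind, cols)
  r <- suppressWarnings(stats::cor(t(model$H), cm))
  r[is.na(r)] <- 0
  dimnames(r) <- list(rownames(model$H), colnames(cm))
  list(technical = apply(abs(r), 1, max) >= threshold, cor = r)
}

#' Project NMF patterns into a new dataset by NNLS
#'
#' Restricts the loadings and the new expression matrix to their shared,
#' identically ordered gene set, then solves, for each new observation, the
#' non-negative least squares problem `min_{h >= 0} ||x - W h||^2` by
#' cyclic coordinate descent with a fixed sweep order (deterministic). This
#' is the transfer-learning step that carries patterns across modalities,
#' regions, and species.
#'
#' @param model an [nmf_fit()] model (or any list with `W`).
#' @param X_new genes x observations matrix with gene rownames (a
#'   `lognorm_matrix` is accepted).
#' @param tol coordinate-descent stopping tolerance.
#' @return list: `H_new` (k x new observations), `genes_used`,
#'   `dropped_genes` (per side counts).
#' @export
project_patterns <- function(model, X_new, tol = 1e-8) {
  if (inherits(X_new, "lognorm_matrix")) X_new <- X_new$values
  if (is.null(rownames(X_new)) || is.null(rownames(model$W))) {
    stop("both the loadings and the new matrix need gene rownames")
  }
  shared <- intersect(rownames(model$W), rownames(X_new))
  if (!length(shared)) {
    stop("empty gene intersection; loadings e.g. ",
         paste(utils::head(rownames(model$W), 3), collapse = ", "),
         " vs target e.g. ",
         paste(utils::head(rownames(X_new), 3), collapse = ", "))
  }
  W <- model$W[shared, , drop = FALSE]
  X <- as.matrix(X_new[shared, , drop = FALSE])
  H_new <- nnls_multi(W, X, tol = tol)
  dimnames(H_new) <- list(colnames(model$W), colnames(X_new))
  list(H_new = H_new,
       genes_used = shared,
       dropped_genes = c(loadings = nrow(model$W) - length(shared),
                         target = nrow(X_new) - length(shared)))
}

# NNLS for every column of X against fixed W, via cyclic coordinate descent
# on the normal equations (all columns updated simultaneously per
# coordinate).
nnls_multi <- function(W, X, tol = 1e-8, max_sweeps = 1000) {
  WtW <- crossprod(W)
  WtX <- crossprod(W, X)
  k <- ncol(W)
  H <- matrix(0, k, ncol(X))
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(k)) {
      d <- WtW[j, j]
      if (d < 1e-12) next
      hj <- pmax(0, H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / d)
      delta <- max(delta, max(abs(hj - H[j, ])))
      H[j, ] <- hj
    }
    if (delta < tol * max(1, max(abs(H)))) break
  }
  H
}

#' Differential expression between spots positive for two patterns
#'
#' Classifies spots as expressing pattern A (`h_a > eps`, `h_b <= eps`) or
#' pattern B (symmetric); doubly-positive spots are excluded and counted.
#' The two classes are pseudobulked by sample and compared with
#' [pairwise_model()] (sign convention: logFC > 0 means higher in class A).
#'
#' @param assay the spot-level `count_assay`.
#' @param h_a,h_b projected pattern weights aligned to the assay's
#'   observations.
#' @param sample_key obs_meta column giving the sample.
#' @param eps positivity threshold (0 = the literal nonzero rule).
#' @param min_obs minimum spots per (class, sample) pseudobulk column.
#' @param covariates passed to [pairwise_model()].
#' @return list: `stats` (DE table, class A vs class B) and `report`
#'   (class sizes, doubly-positive count, dropped columns).
#' @export
nmf_positive_de <- function(assay, h_a, h_b, sample_key = "sample", eps = 0,
                            min_obs = 10, covariates = character()) {
  stopifnot(length(h_a) == ncol(assay$counts),
            length(h_b) == ncol(assay$counts))
  class_a <- h_a > eps & h_b <= eps
  class_b <- h_b > eps & h_a <= eps
  double_pos <- h_a > eps & h_b > eps
  if (!any(class_a) || !any(class_b)) {
    stop(sprintf(
      "empty class (A: %d, B: %d spots; %d doubly positive)",
      sum(class_a), sum(class_b), sum(double_pos)
    ))
  }
  sel <- which(class_a | class_b)
  sub <- subset_assay(assay, obs = sel)
  sub$obs_meta$nmf_class <- ifelse(class_a[sel], "A", "B")
  pb <- pseudobulk(sub, group_key = "nmf_class", sample_key = sample_key,
                   min_obs = min_obs)
  stats <- pairwise_model(pb, "A", "B", covariates = covariates)
  list(stats = stats,
       report = list(n_a = sum(class_a), n_b = sum(class_b),
                     n_double_positive = sum(double_pos),
                     n_neither = sum(!class_a & !class_b & !double_pos),
                     dropped_columns = pb$dropped_columns))
}

#' Per-sample fraction of pattern-positive observations by group
#'
#' For each (sample, group) cell, the fraction of observations with weight
#' strictly above zero. Empty cells are `NA`, never 0.
#'
#' @param h pattern weights.
#' @param group_labels,sample_labels aligned label vectors.
#' @return samples x groups matrix of fractions.
#' @export
fraction_nonzero_by_group <- function(h, group_labels, sample_labels) {
  tapply(h > 0, list(factor(sample_labels), factor(group_labels)), mean)
}

#' Per-sample mean pattern weight by group (nuclei variant)
#'
#' @inheritParams fraction_nonzero_by_group
#' @return samples x groups matrix of mean weights (`NA` for empty cells).
#' @export
mean_weight_by_group <- function(h, group_labels, sample_labels) {
  tapply(h, list(factor(sample_labels), factor(group_labels)), mean)
}
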