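#' Per-observation quality-control metrics
#'
#' Computes library size (`sum`, total UMIs), number of detected genes
#' (`detected`, genes with count > 0) and the mitochondrial expression rate
#' (`mito_pct`, percent of UMIs on mito-flagged genes) for every observation.
#'
#' @param assay a `count_assay`; mitochondrial genes are taken from the
#'   logical `mito` column of `gene_meta` (warned and treated as none if
#'   absent or all-FALSE).
#' @return data.frame with columns `obs_id`, `sum`, `detected`, `mito_pct`.
#' @export
compute_qc <- function(assay) {
  m <- assay$counts
  total <- Matrix::colSums(m)
  detected <- Matrix::colSums(m > 0)
  mito <- assay$gene_meta$mito
  if (is.null(mito) || !any(mito, na.rm = TRUE)) {
    warning("no mito-flagged genes; mito_pct set to 0")
    mito_sum <- rep(0, ncol(m))
  } else {
    mito_sum <- Matrix::colSums(m[which(mito), , drop = FALSE])
  }
  mito_pct <- ifelse(total > 0, 100 * mito_sum / total, 0)
  data.frame(obs_id = assay$obs_ids, sum = total, detected = detected,
             mito_pct = mito_pct, row.names = assay$obs_ids)
}

#' Flag outliers by median absolute deviation
#'
#' Flags values strictly beyond `median +/- nmads * MAD` on the chosen side,
#' using the 1.4826 consistency constant. A zero MAD (more than half the
#' values tied at the median) is degenerate and warned about; the strict
#' rule still applies, so a constant vector flags nothing while any value
#' off the median is flagged.
#'
#' @param values finite numeric vector.
#' @param nmads number of MADs.
#' @param side `"both"`, `"lower"` or `"higher"`.
#' @param log_transform apply `log1p` before computing the threshold.
#' @return logical flags, same length as `values`.
#' @export
mad_outlier <- function(values, nmads = 3,
                        side = c("both", "lower", "higher"),
                        log_transform = FALSE) {
  side <- match.arg(side)
  stopifnot(all(is.finite(values)))
  v <- if (log_transform) log1p(values) else values
  med <- stats::median(v)
  md <- stats::mad(v, constant = 1.4826)
  if (md == 0) {
    warning("MAD is zero; thresholds collapse to the median")
  }
  lo <- v < med - nmads * md
  hi <- v > med + nmads * md
  switch(side, both = lo | hi, lower = lo, higher = hi)
}

#' Hard spot filter for SRT capture areas
#'
#' Removes, in priority order: out-of-tissue spots, all-zero spots, spots
#' with fewer than `min_detected` detected genes, spots with fewer than
#' `min_sum` total UMIs (both strict "less than", so a spot at the threshold
#' is retained), and spots with a 100 percent mitochondrial rate. Genes with
#' zero total count across the retained spots are then dropped. A per-reason
#' removal histogram is attached as attribute `filter_report`; each removed
#' spot is counted once, under the first reason that applies.
#'
#' @param sample a `spatial_sample`.
#' @param min_detected,min_sum hard thresholds (spots kept iff metric >=
#'   threshold).
#' @param drop_mito100 remove spots whose UMIs are 100 percent mitochondrial.
#' @return filtered `spatial_sample` with attribute `filter_report`
#'   (data.frame reason/removed).
#' @export
filter_spots <- function(sample, min_detected = 20, min_sum = 20,
                         drop_mito100 = TRUE) {
  qc <- suppressWarnings(compute_qc(sample$assay))
  reason <- rep(NA_character_, nrow(qc))
  mark <- function(cond, label) {
    hit <- cond & is.na(reason)
    reason[hit] <<- label
  }
  mark(!sample$in_tissue, "out_of_tissue")
  mark(qc$sum == 0, "all_zero")
  mark(qc$detected < min_detected, "low_detected")
  mark(qc$sum < min_sum, "low_sum")
  if (drop_mito100) mark(qc$mito_pct >= 100 & qc$sum > 0, "mito_100")
  keep <- is.na(reason)
  report <- as.data.frame(table(
    factor(reason[!keep],
           levels = c("out_of_tissue", "all_zero", "low_detected",
                      "low_sum", "mito_100"))
  ), stringsAsFactors = FALSE)
  names(report) <- c("reason", "removed")
  if (!any(keep)) {
    stop("all spots removed: ",
         paste(sprintf("%s=%d", report$reason, report$removed),
               collapse = ", "))
  }
  out <- subset_sample(sample, obs = which(keep))
  gene_keep <- Matrix::rowSums(out$assay$counts) > 0
  out <- subset_sample(out, genes = which(gene_keep))
  attr(out, "filter_report") <- report
  attr(out, "genes_removed") <- sum(!gene_keep)
  out
}

#' Knee and cliff points of a barcode-rank curve
#'
#' On the log-rank versus log-total curve (ties collapsed to one rank), the
#' cliff is the point of steepest descent (most negative first derivative of
#' a smoothing-spline fit) and the knee is the point of minimum signed
#' curvature at ranks at or above the cliff's total (i.e. to its left).
#' Returned as UMI count thresholds; barcodes with total below the knee are
#' droppable, mirroring knee-point empty-droplet filtering.
#'
#' @param total_counts_per_barcode numeric vector of per-barcode totals
#'   (>= 100 barcodes).
#' @param df degrees of freedom of the smoothing spline (default scales with
#'   the number of distinct totals).
#' @return list with `knee` and `cliff` count thresholds.
#' @export
knee_threshold <- function(total_counts_per_barcode, df = NULL) {
  totals <- total_counts_per_barcode[total_counts_per_barcode > 0]
  if (length(totals) < 100) stop("need at least 100 barcodes")
  tab <- sort(unique(totals), decreasing = TRUE)
  # rank of each distinct total = number of barcodes with at least that total
  rank_of <- vapply(tab, function(t) sum(totals >= t), numeric(1))
  x <- log10(rank_of)
  y <- log10(tab)
  if (length(x) < 8) stop("too few distinct totals to locate a knee")
  if (is.null(df)) df <- max(4, min(20, floor(length(x) / 4)))
  fit <- stats::smooth.spline(x, y, df = df)
  d1 <- stats::predict(fit, x, deriv = 1)$y
  d2 <- stats::predict(fit, x, deriv = 2)$y
  curv <- d2 / (1 + d1^2)^1.5
  cliff_i <- which.min(d1)
  cand <- seq_len(cliff_i)
  knee_i <- cand[which.min(curv[cand])]
  # a knee requires a clearly concave transition; near-linear curves (or
  # mild wiggles from tie collapsing) have |curvature| well below this
  if (min(curv[cand]) > -2) {
    stop("no knee: barcode-rank curve has no concave transition")
  }
  list(knee = tab[knee_i], cliff = tab[cliff_i])
}

#' Rank genes by Poisson deviance under a constant-proportion null
#'
#' For gene g with counts y_gj and column totals n_j, the null rate is
#' mu_gj = n_j * pi_g with pi_g = sum_j y_gj / sum_j n_j, and the deviance is
#' D_g = 2 * sum_j (y_gj * log(y_gj / mu_gj) - (y_gj - mu_gj)), with
#' 0 * log 0 = 0. Genes whose counts are exactly proportional to the column
#' totals have D = 0; highly deviant genes are informative features.
#'
#' @param assay a `count_assay`.
#' @param n_top number of top genes to return (all, with a warning, if it
#'   exceeds the gene count).
#' @return data.frame (gene, deviance) sorted by deviance, top `n_top` rows.
#' @export
poisson_deviance_selection <- function(assay, n_top = 2000) {
  m <- assay$counts
  n_j <- Matrix::colSums(m)
  pi_g <- Matrix::rowSums(m) / sum(n_j)
  # sum_j (y - mu) = 0 because mu shares the gene's total, so only the
  # y * log(y / mu) terms over nonzero entries contribute
  tr <- Matrix::summary(m)
  mu <- n_j[tr$j] * pi_g[tr$i]
  contrib <- 2 * tr$x * log(tr$x / mu)
  dev <- vapply(split(contrib, factor(tr$i, levels = seq_len(nrow(m)))),
                sum, numeric(1))
  dev[!is.finite(dev)] <- 0
  out <- data.frame(gene = assay$gene_ids, deviance = dev)
  out <- out[order(-out$deviance, out$gene), , drop = FALSE]
  if (n_top > nrow(out)) {
    warning("n_top exceeds the gene count; returning all genes")
    n_top <- nrow(out)
  }
  rownames(out) <- NULL
  out[seq_len(n_top), , drop = FALSE]
}

#' Pearson residuals under the constant-proportion Poisson null
#'
#' r_gj = (y_gj - mu_gj) / sqrt(mu_gj) with mu_gj = n_j * pi_g as in
#' [poisson_deviance_selection()]. Columns with zero total give zero
#' residuals. The residual matrix is the usual input to PCA as a GLM-PCA
#' approximation.
#'
#' @param assay a `count_assay`.
#' @return dense genes x observations residual matrix.
#' @export
null_pearson_residuals <- function(assay) {
  m <- as.matrix(assay$counts)
  n_j <- colSums(m)
  pi_g <- rowSums(m) / sum(n_j)
  mu <- outer(pi_g, n_j)
  r <- (m - mu) / sqrt(mu)
  r[mu == 0] <- 0
  dimnames(r) <- dimnames(m)
  r
}
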