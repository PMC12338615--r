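#' Per-sample expression filter for SVG scoring
#'
#' Retains genes with at least `min_count` counts in at least
#' `ceil(min_prop * n_spots)` spatial locations, applied per sample only.
#'
#' @param sample a `spatial_sample` (already spot-filtered).
#' @param min_count minimum count defining an "expressing" spot.
#' @param min_prop minimum proportion of spots.
#' @return filtered `spatial_sample`.
#' @export
per_sample_gene_filter <- function(sample, min_count = 3, min_prop = 0.005) {
  m <- sample$assay$counts
  need <- ceiling(min_prop * ncol(m))
  n_expr <- Matrix::rowSums(m >= min_count)
  keep <- n_expr >= need
  if (!any(keep)) stop("all genes removed by the expression filter")
  subset_sample(sample, genes = which(keep))
}

# symmetrized k-nearest-neighbour weight matrix, row-normalized
knn_weights <- function(xy, k) {
  n <- nrow(xy)
  if (n < k + 1) stop("need at least k_neighbors + 1 spots")
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    adj[i, order(d[i, ])[seq_len(k)]] <- 1
  }
  adj <- pmax(adj, t(adj))       # j ~ i if either is a kNN of the other
  adj / rowSums(adj)
}

#' Score spatial variability of every gene by Moran's I
#'
#' Moran's I of each gene's log-normalized expression on the symmetrized
#' k-nearest-neighbour spot graph with row-normalized weights (a stand-in
#' scorer for Gaussian-process spatial-variance ranking; the downstream rank
#' aggregation accepts any per-sample rank table). Genes are ranked by score
#' descending, ties broken by mean expression (descending) then gene id.
#' Constant genes score 0 and carry a degenerate flag.
#'
#' @param sample a `spatial_sample`.
#' @param k_neighbors neighbours per spot (default 6, the hexagonal Visium
#'   lattice).
#' @param lognorm optional precomputed [log_normalize()] result for the
#'   sample's assay.
#' @return data.frame (gene, score, mean_expr, degenerate, rank).
#' @export
spatial_variability_score <- function(sample, k_neighbors = 6,
                                      lognorm = NULL) {
  if (is.null(lognorm)) lognorm <- log_normalize(sample$assay)
  V <- as.matrix(lognorm$values)
  W <- knn_weights(sample$xy, k_neighbors)
  Z <- V - rowMeans(V)
  num <- rowSums((Z %*% t(W)) * Z)
  den <- rowSums(Z^2)
  degenerate <- den == 0
  score <- ifelse(degenerate, 0, num / den)
  out <- data.frame(
    gene = sample$assay$gene_ids, score = score,
    mean_expr = rowMeans(V), degenerate = degenerate
  )
  ord <- order(-out$score, -out$mean_expr, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Aggregate per-sample SVG rankings across samples
#'
#' Computes each gene's mean rank across samples and the number of samples
#' where it ranks within the top `top_cut`; a gene is "replicated" when that
#' count reaches `min_samples`. A gene filtered out of a sample contributes
#' that sample's gene count + 1 to the mean (mode `"all"`); mode
#' `"present"` averages only over samples that scored the gene.
#'
#' @param per_sample_results list of [spatial_variability_score()] tables.
#' @param top_cut rank cut defining "highly ranked" in one sample.
#' @param min_samples samples required for replication.
#' @param mean_mode `"all"` (absent genes penalized) or `"present"`.
#' @return data.frame (gene, mean_rank, n_top_samples, replicated), ordered
#'   replicated-first by mean rank.
#' @export
aggregate_svg <- function(per_sample_results, top_cut = 1000,
                          min_samples = 2, mean_mode = c("all", "present")) {
  mean_mode <- match.arg(mean_mode)
  if (length(per_sample_results) < 2) stop("need at least 2 samples")
  genes <- sort(unique(unlist(lapply(per_sample_results, `[[`, "gene"))))
  rank_mat <- matrix(NA_real_, length(genes), length(per_sample_results),
                     dimnames = list(genes, NULL))
  for (s in seq_along(per_sample_results)) {
    r <- per_sample_results[[s]]
    rank_mat[match(r$gene, genes), s] <- r$rank
  }
  n_top <- rowSums(rank_mat <= top_cut, na.rm = TRUE)
  if (mean_mode == "all") {
    g_s <- vapply(per_sample_results, nrow, numeric(1))
    filled <- rank_mat
    for (s in seq_along(per_sample_results)) {
      filled[is.na(filled[, s]), s] <- g_s[s] + 1
    }
    mean_rank <- rowMeans(filled)
  } else {
    mean_rank <- rowMeans(rank_mat, na.rm = TRUE)
  }
  out <- data.frame(
    gene = genes, mean_rank = mean_rank, n_top_samples = n_top,
    replicated = n_top >= min_samples, row.names = NULL
  )
  out[order(-out$replicated, out$mean_rank, out$gene), , drop = FALSE]
}
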