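#' Neighborhood purity of a clustering
#'
#' For every observation, the fraction of its k nearest Euclidean neighbours
#' (in the supplied embedding) sharing its label; per-cluster purity is the
#' mean over the cluster's members. Reported as the same-label fraction
#' (1 = pure); the complementary different-label fraction is included to
#' avoid sign confusion.
#'
#' @param embedding numeric matrix, observations x dimensions.
#' @param labels cluster labels, one per row.
#' @param k neighbours (k < n).
#' @return list with `per_obs` purity vector, `per_cluster` data.frame
#'   (cluster, purity, impurity, n, small_cluster flag) and `mean` purity.
#' @export
neighbor_purity <- function(embedding, labels, k = 50) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.character(labels)
  stopifnot(length(labels) == n, k < n)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  per_obs <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1))
  agg <- tapply(per_obs, labels, mean)
  sizes <- table(labels)[names(agg)]
  per_cluster <- data.frame(
    cluster = names(agg), purity = as.numeric(agg),
    impurity = 1 - as.numeric(agg), n = as.integer(sizes),
    small_cluster = as.integer(sizes) < 2, row.names = NULL
  )
  list(per_obs = per_obs, per_cluster = per_cluster, mean = mean(agg))
}

#' H+ cluster discordance
#'
#' Estimates `P(D_within > D_between)` (ties counted half): the probability
#' that a uniformly sampled same-label pair is farther apart than a
#' different-label pair. Zero for perfectly separated clusters; 0.5 when
#' labels are independent of geometry. Exact enumeration is used when the
#' total number of pairs is at most `2 * n_pairs`; otherwise both pair
#' populations are subsampled with the given seed.
#'
#' @param x embedding matrix (observations x dims), `dist` object, or square
#'   distance matrix.
#' @param labels cluster labels (>= 2 distinct).
#' @param n_pairs Monte-Carlo sample size per pair population.
#' @param seed seed for the subsampling.
#' @return list with `h_plus`, `exact` flag and `n_pairs_sampled`.
#' @export
h_plus <- function(x, labels, n_pairs = 1e5, seed = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (inherits(x, "dist")) {
    d <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    d <- if (nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x))) &&
             all(diag(x) == 0) && nrow(x) == length(labels)) {
      x
    } else {
      as.matrix(stats::dist(x))
    }
  }
  stopifnot(nrow(d) == length(labels))
  n <- nrow(d)
  ut <- upper.tri(d)
  same <- outer(labels, labels, `==`)
  dw <- d[ut & same]
  db <- d[ut & !same]
  if (!length(dw) || !length(db)) stop("need both within- and between-cluster pairs")
  total_pairs <- n * (n - 1) / 2
  if (total_pairs <= 2 * n_pairs) {
    # exact: P(W > B) + 0.5 P(W == B) via sorted counting
    sb <- sort(db)
    gt <- findInterval(dw, sb, left.open = TRUE)          # b strictly below w
    ge <- findInterval(dw, sb)                            # b at or below w
    n_cmp <- as.numeric(length(dw)) * as.numeric(length(db))
    hp <- sum(gt + 0.5 * (ge - gt)) / n_cmp
    list(h_plus = hp, exact = TRUE, n_pairs_sampled = n_cmp)
  } else {
    set.seed(seed)
    w <- dw[sample.int(length(dw), n_pairs, replace = TRUE)]
    b <- db[sample.int(length(db), n_pairs, replace = TRUE)]
    hp <- mean(w > b) + 0.5 * mean(w == b)
    list(h_plus = hp, exact = FALSE, n_pairs_sampled = n_pairs)
  }
}
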