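#' Gate anchor-positive cells by k-means on copy count and intensity
#'
#' Clusters cells at `k` on the anchor gene's (copy count, intensity) pair
#' (features standardized to unit variance by default; seeded with multiple
#' restarts, best inertia kept), ranks clusters by centroid copy count, and
#' calls the top `n_keep` clusters positive. The implied minimum copy count
#' and minimum intensity among positives are reported, mirroring the
#' layer-gating step that restricts analysis to the anchor-marked layer.
#'
#' @param cells smFISH cell table with `<gene>_copies` / `<gene>_intensity`
#'   columns.
#' @param anchor_gene the anchor gene name.
#' @param k number of k-means clusters.
#' @param n_keep clusters (from the top by copy-count centroid) called
#'   positive.
#' @param standardize standardize the two features first.
#' @param seed,nstart k-means seeding and restarts.
#' @return list: `positive` (logical per cell), `implied_thresholds`
#'   (min_copies, min_intensity among positives), `centers`, `cluster`.
#' @export
anchor_gate <- function(cells, anchor_gene, k = 3, n_keep = 2,
                        standardize = TRUE, seed = 1, nstart = 20) {
  copies <- cells[[paste0(anchor_gene, "_copies")]]
  intens <- cells[[paste0(anchor_gene, "_intensity")]]
  if (is.null(copies) || is.null(intens)) {
    stop("cells lack copy/intensity columns for ", anchor_gene)
  }
  feats <- cbind(copies = copies, intensity = intens)
  if (nrow(unique(feats)) < k) {
    stop("fewer than k distinct (copy, intensity) points; cannot gate")
  }
  fs <- feats
  if (standardize) {
    sds <- apply(feats, 2, stats::sd)
    sds[sds == 0] <- 1
    fs <- sweep(feats, 2, sds, `/`)
  }
  set.seed(seed)
  km <- stats::kmeans(fs, centers = k, nstart = nstart, iter.max = 100)
  centroid_copies <- tapply(copies, km$cluster, mean)
  top <- as.integer(names(sort(centroid_copies, decreasing = TRUE)))[seq_len(n_keep)]
  positive <- km$cluster %in% top
  list(
    positive = positive,
    implied_thresholds = c(min_copies = min(copies[positive]),
                           min_intensity = min(intens[positive])),
    centers = km$centers, cluster = km$cluster
  )
}

# segment intersection test for the self-intersection check (proper
# crossings only; shared endpoints of adjacent edges do not count)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

point_on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-9) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  if (abs(cross) > eps * max(1, abs(bx - ax), abs(by - ay))) return(FALSE)
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}

#' Restrict cells to a polygon (drawn or automatic)
#'
#' Point-in-polygon by the even-odd (ray casting) rule, with points on the
#' boundary counted inside. `polygon = NULL` uses auto mode: the convex hull
#' of the anchor-positive cells, the programmatic analogue of drawing a
#' polygon around the gated cells. Manual polygons are rejected if
#' self-intersecting.
#'
#' @param cells cell table with `x`, `y`.
#' @param polygon two-column vertex matrix (closed implicitly), or `NULL`.
#' @param anchor_positive logical per cell; required in auto mode.
#' @return logical `in_polygon` flags.
#' @export
polygon_restrict <- function(cells, polygon = NULL, anchor_positive = NULL) {
  if (is.null(polygon)) {
    if (is.null(anchor_positive) || !any(anchor_positive)) {
      stop("auto mode needs anchor_positive flags with at least one positive")
    }
    pts <- cbind(cells$x, cells$y)[anchor_positive, , drop = FALSE]
    polygon <- pts[grDevices::chull(pts), , drop = FALSE]
  } else {
    polygon <- as.matrix(polygon)
    nv <- nrow(polygon)
    if (nv >= 4) {
      for (i in seq_len(nv)) {
        for (j in seq_len(nv)) {
          if (abs(i - j) <= 1 || (i == 1 && j == nv) || (i == nv && j == 1)) next
          if (segments_cross(polygon[i, ], polygon[i %% nv + 1, ],
                             polygon[j, ], polygon[j %% nv + 1, ])) {
            stop("polygon is self-intersecting")
          }
        }
      }
    }
  }
  vx <- polygon[, 1]; vy <- polygon[, 2]
  nv <- length(vx)
  vapply(seq_len(nrow(cells)), function(i) {
    px <- cells$x[i]; py <- cells$y[i]
    inside <- FALSE
    j <- nv
    for (v in seq_len(nv)) {
      if (point_on_segment(px, py, vx[v], vy[v], vx[j], vy[j])) return(TRUE)
      if ((vy[v] > py) != (vy[j] > py)) {
        xint <- (vx[j] - vx[v]) * (py - vy[v]) / (vy[j] - vy[v]) + vx[v]
        if (px < xint) inside <- !inside
      }
      j <- v
    }
    inside
  }, logical(1))
}

#' Scale copy counts by relative cell area
#'
#' `scaled = copies / (area / median_area)`, the median taken over the
#' sample's in-polygon cells, so larger cells are down-weighted (the
#' multiplicative reading `copies * area / median_area` is available via
#' `mode`).
#'
#' @param cells cell table.
#' @param genes genes whose `<gene>_copies` columns to scale.
#' @param in_polygon logical; cells over which the median is taken (default
#'   all).
#' @param mode `"divide"` (default) or `"multiply"`.
#' @return the cell table with added `<gene>_scaled` columns.
#' @export
scale_by_area <- function(cells, genes, in_polygon = NULL,
                          mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  if (is.null(in_polygon)) in_polygon <- rep(TRUE, nrow(cells))
  stopifnot(all(cells$area > 0))
  med <- stats::median(cells$area[in_polygon])
  rel <- cells$area / med
  for (g in genes) {
    cp <- cells[[paste0(g, "_copies")]]
    cells[[paste0(g, "_scaled")]] <- if (mode == "divide") cp / rel else cp * rel
  }
  cells
}

#' Call expressors with a two-component Gaussian mixture
#'
#' Fits a one-dimensional two-component Gaussian mixture by EM (k-means++
#' style seeded initialization, multiple restarts, best log-likelihood kept,
#' variance floor) to area-scaled copy counts and calls a cell "expressing"
#' when its posterior for the higher-mean component reaches 0.5. Copy counts
#' of highly expressed genes saturate, so the mixture call replaces any hard
#' copy threshold. All-identical input is degenerate: every cell is called
#' non-expressing and flagged.
#'
#' @param x numeric vector (>= 10 values) of scaled copies for one gene in
#'   one sample.
#' @param n_restarts EM restarts.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param var_floor variance floor.
#' @param seed seed for the restarts.
#' @return list: `expressing` (logical), `params` (means, sds, weights),
#'   `posterior`, `degenerate`, `loglik`.
#' @export
gmm_expressor_call <- function(x, n_restarts = 10, tol = 1e-8,
                               var_floor = 1e-6, seed = 1) {
  if (length(x) < 10) stop("need at least 10 cells")
  if (stats::sd(x) == 0) {
    return(list(expressing = rep(FALSE, length(x)),
                params = NULL, posterior = NULL,
                degenerate = TRUE, loglik = NA_real_))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # k-means++ style pair: first center uniform, second weighted by
    # squared distance
    m1 <- x[sample.int(length(x), 1)]
    w <- (x - m1)^2
    m2 <- if (sum(w) > 0) x[sample.int(length(x), 1, prob = w)] else m1 + 1
    fit <- em_gmm2(x, c(m1, m2), tol = tol, var_floor = var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  hi <- which.max(best$mu)
  post_hi <- best$posterior[, hi]
  list(expressing = post_hi >= 0.5,
       params = list(mu = best$mu, sd = sqrt(best$sigma2), pi = best$pi),
       posterior = best$posterior, degenerate = FALSE, loglik = best$loglik)
}

em_gmm2 <- function(x, mu, tol, var_floor, max_iter = 500) {
  n <- length(x)
  sigma2 <- rep(max(stats::var(x) / 4, var_floor), 2)
  pi_k <- c(0.5, 0.5)
  ll_prev <- -Inf
  post <- matrix(0.5, n, 2)
  for (it in seq_len(max_iter)) {
    dens <- cbind(pi_k[1] * stats::dnorm(x, mu[1], sqrt(sigma2[1])),
                  pi_k[2] * stats::dnorm(x, mu[2], sqrt(sigma2[2])))
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    post <- dens / rs
    ll <- sum(log(rs))
    nk <- colSums(post)
    nk[nk == 0] <- 1e-12
    mu <- colSums(post * x) / nk
    sigma2 <- pmax(colSums(post * (x - rep(mu, each = n))^2) / nk, var_floor)
    pi_k <- nk / n
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
  }
  list(mu = mu, sigma2 = sigma2, pi = pi_k, posterior = post, loglik = ll)
}

#' Coexpression statistics over expressor calls
#'
#' From a logical calls matrix (cells x genes) computes: the proportion of
#' cells expressing exactly two and all of the genes; the pairwise
#' conditional matrix `conditional[i, j]` = proportion of gene-i expressors
#' that also express gene j (row undefined, `NA`, when gene i has no
#' expressors; diagonal 1 where defined); and the pairwise Spearman
#' correlation (average-rank ties) of the scaled copies.
#'
#' @param calls logical matrix, cells x genes.
#' @param scaled numeric matrix of scaled copies, same shape.
#' @return list: `prop_exactly2`, `prop_all`, `conditional`, `spearman`.
#' @export
coexpression_stats <- function(calls, scaled = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  ne <- rowSums(calls)
  cond <- matrix(NA_real_, m, m, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(m)) {
    ni <- sum(calls[, i])
    if (ni == 0) next
    cond[i, ] <- colSums(calls[calls[, i], , drop = FALSE]) / ni
  }
  sp <- if (is.null(scaled)) NULL else stats::cor(as.matrix(scaled),
                                                  method = "spearman")
  list(prop_exactly2 = mean(ne == m - 1 & m >= 2),
       prop_all = mean(ne == m),
       conditional = cond, spearman = sp)
}

#' Average per-sample conditional coexpression matrices
#'
#' Element-wise mean across samples, ignoring undefined (`NA`) rows.
#'
#' @param cond_list list of conditional matrices from
#'   [coexpression_stats()].
#' @return averaged matrix.
#' @export
average_coexpression <- function(cond_list) {
  arr <- simplify2array(cond_list)
  apply(arr, c(1, 2), mean, na.rm = TRUE)
}
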