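test_that("HALS recovers exact low-rank structure deterministically", {
  set.seed(40)
  w <- rexp(60)
  h <- rexp(30)
  X <- outer(w, h)
  m <- nmf_fit(X, k = 1, seed = 1, max_iter = 300)
  expect_lt(sqrt(sum((X - m$W %*% m$H)^2)) / sqrt(sum(X^2)), 1e-4)

  m2 <- nmf_fit(X, k = 1, seed = 1, max_iter = 300)
  expect_identical(m$W, m2$W)
  expect_identical(m$H, m2$H)

  expect_error(nmf_fit(X, k = 40), "smaller than")
  expect_error(nmf_fit(X - 10, k = 1), "non-negative")
})

test_that("planted block factors are recovered up to permutation", {
  set.seed(41)
  Wt <- matrix(0, 200, 4)
  for (j in 1:4) Wt[((j - 1) * 50 + 1):(j * 50), j] <- rexp(50) + 0.5
  Ht <- matrix(rexp(4 * 150), 4, 150)
  X <- Wt %*% Ht + matrix(abs(rnorm(200 * 150, 0, 0.05)), 200)
  m <- nmf_fit(X, k = 4, seed = 2, max_iter = 400)
  # exhaustive best-permutation cosine matching (4! candidates)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  best <- max(apply(perms, 1, function(p) {
    mean(vapply(1:4, function(j) cos(Wt[, j], m$W[, p[j]]), numeric(1)))
  }))
  expect_gte(best, 0.9)
  # objective trace never increases
  expect_true(all(diff(m$objective_trace) <= 1e-9 * m$objective_trace[1]))
})

test_that("speckled cross-validation selects the planted rank", {
  set.seed(42)
  Wt <- matrix(rexp(300 * 3), 300, 3)
  Ht <- matrix(rexp(3 * 200), 3, 200)
  lam <- Wt %*% Ht
  X <- matrix(rpois(length(lam), lam), nrow(lam))
  cv <- cross_validate_rank(X, ranks = 1:5, seed = 7, n_reps = 2,
                            max_iter = 80, tol = 1e-4)
  expect_equal(cv$selected, 3)
  # identical seeds give identical error curves
  cv2 <- cross_validate_rank(X, ranks = 1:5, seed = 7, n_reps = 2,
                             max_iter = 80, tol = 1e-4)
  expect_identical(cv$per_rank, cv2$per_rank)

  # rank 1 on rank-1 Poisson data: held-out MSE approximates the noise
  # variance (= the mean rate under Poisson noise)
  w1 <- rexp(300) + 0.5
  h1 <- rexp(200) + 0.5
  lam1 <- outer(w1, h1) * 3
  X1 <- matrix(rpois(length(lam1), lam1), 300)
  cv1 <- cross_validate_rank(X1, ranks = 1, seed = 3, n_reps = 2,
                             max_iter = 120, tol = 1e-5)
  expect_lt(abs(cv1$per_rank$mean_mse - mean(lam1)) / mean(lam1), 0.15)
})

test_that("pattern annotation assigns indicators and breaks ties as documented", {
  H <- rbind(P1 = c(1, 1, 0, 0), P2 = c(0, 0, 1, 1))
  W <- matrix(rexp(20), 10, 2,
              dimnames = list(paste0("g", 1:10), c("P1", "P2")))
  model <- list(W = W, H = H, k = 2)
  ann <- annotate_patterns(model, c("c1", "c1", "c2", "c2"))
  expect_identical(unname(ann$top_pattern), c("P1", "P2"))
  expect_equal(unname(ann$mean_weights["P1", ]), c(1, 0))

  # two identical patterns: tie broken by specificity then lower index
  H2 <- rbind(P1 = c(1, 1, 2, 2), P2 = c(1, 1, 2, 2))
  model2 <- list(W = W, H = H2, k = 2)
  ann2 <- annotate_patterns(model2, c("c1", "c1", "c2", "c2"))
  expect_identical(unname(ann2$top_pattern["c2"]), "P1")

  # technical patterns are excluded from assignment
  ann3 <- annotate_patterns(model, c("c1", "c1", "c2", "c2"),
                            technical = c(TRUE, FALSE))
  expect_identical(unname(ann3$top_pattern), c("P2", "P2"))
})

test_that("technical patterns are flagged by covariate correlation", {
  set.seed(43)
  lib <- rlnorm(200)
  H <- rbind(P1 = lib, P2 = rexp(200))
  model <- list(W = matrix(1, 5, 2), H = H, k = 2)
  tf <- technical_filter(model, data.frame(libsize = lib,
                                           donor = rep(c("a", "b"), 100)))
  expect_true(tf$technical[1])
  expect_equal(unname(tf$cor["P1", "libsize"]), 1)
  expect_false(tf$technical[2])

  # zero-variance pattern: correlation treated as 0, not flagged
  H3 <- rbind(P1 = rep(2, 200), P2 = rexp(200))
  tf3 <- technical_filter(list(W = model$W, H = H3, k = 2),
                          data.frame(libsize = lib))
  expect_false(tf3$technical[1])
})

test_that("planted library-size factors are flagged across seeds", {
  hits <- 0
  for (s in 1:10) {
    si <- simulate_paired_regions(sim_config(
      n_donors = 3, n_genes = 600, markers_per_layer = 40, flat_genes = 100,
      n_nuclei_per_donor = 200, seed = s
    ))
    mod <- nmf_fit(log_normalize(si$nuclei), k = 12, seed = s,
                   max_iter = 120, tol = 1e-5)
    qc <- compute_qc(si$nuclei)
    tf <- technical_filter(mod, data.frame(
      sum = qc$sum, mito_pct = qc$mito_pct,
      donor = si$nuclei$obs_meta$donor, sex = si$nuclei$obs_meta$sex
    ))
    if (any(tf$technical)) {
      hit <- any(vapply(which(tf$technical), function(j) {
        top <- rownames(mod$W)[order(-mod$W[, j])[1:20]]
        mean(top %in% si$truth$technical_genes) >= 0.5
      }, logical(1)))
      hits <- hits + hit
    }
  }
  expect_gte(hits, 9)
})

test_that("NNLS projection solves its exact cases and symmetries", {
  set.seed(44)
  W <- matrix(rexp(50 * 3), 50, 3,
              dimnames = list(sprintf("g%02d", 1:50), paste0("P", 1:3)))
  # x proportional to one loading column recovers a scaled unit vector
  x <- 2.5 * W[, 2, drop = FALSE]
  pr <- project_patterns(list(W = W), x)
  expect_equal(unname(pr$H_new[, 1]), c(0, 2.5, 0), tolerance = 1e-6)
  # zero target gives zero weights
  pr0 <- project_patterns(list(W = W), x * 0)
  expect_equal(max(abs(pr0$H_new)), 0)

  # equivariant to a simultaneous gene permutation
  X <- matrix(rexp(50 * 7), 50, 7, dimnames = list(rownames(W), NULL))
  p1 <- project_patterns(list(W = W), X)
  perm <- sample(50)
  p2 <- project_patterns(list(W = W[perm, ]), X[perm, ])
  expect_equal(p1$H_new, p2$H_new, tolerance = 1e-9)

  # disjoint gene sets are an error naming examples from both sides
  X2 <- X
  rownames(X2) <- paste0("other", 1:50)
  expect_error(project_patterns(list(W = W), X2), "empty gene intersection")
})

test_that("self-projection reproduces the training weights", {
  set.seed(45)
  Wt <- matrix(0, 120, 3)
  for (j in 1:3) Wt[((j - 1) * 40 + 1):(j * 40), j] <- rexp(40) + 0.5
  Ht <- matrix(rexp(3 * 100), 3, 100)
  X <- Wt %*% Ht + matrix(abs(rnorm(120 * 100, 0, 0.02)), 120)
  rownames(X) <- sprintf("g%03d", 1:120)
  m <- nmf_fit(X, k = 3, seed = 5, max_iter = 300)
  pr <- project_patterns(m, X)
  for (j in 1:3) {
    expect_gte(cor(pr$H_new[j, ], m$H[j, ]), 0.95)
  }
})

test_that("pattern-positive classification excludes doubly positive spots", {
  set.seed(46)
  counts <- matrix(rpois(40 * 30, 10), 40, 30)
  a <- count_assay(counts, gene_ids = sprintf("g%02d", 1:40),
                   obs_ids = sprintf("o%02d", 1:30),
                   obs_meta = data.frame(sample = rep(c("s1", "s2"), 15)))
  h_a <- c(rep(1, 14), rep(0, 16))
  h_b <- c(rep(0, 14), rep(1, 16))
  de <- nmf_positive_de(a, h_a, h_b, sample_key = "sample", min_obs = 2)
  expect_equal(de$report$n_double_positive, 0)
  expect_equal(de$report$n_a, 14)

  expect_error(nmf_positive_de(a, rep(1, 30), rep(1, 30),
                               sample_key = "sample"), "empty class")
})

test_that("nonzero fractions and mean weights aggregate per sample and group", {
  h <- c(rep(0, 10), rep(2, 10))
  grp <- rep(c("L5", "WM"), 10)
  smp <- rep(c("s1", "s2"), each = 10)
  fr <- fraction_nonzero_by_group(h, grp, smp)
  expect_equal(fr["s1", "L5"], 0)
  expect_equal(fr["s2", "WM"], 1)
  # 3 of 10 positive
  h2 <- c(rep(1, 3), rep(0, 7))
  fr2 <- fraction_nonzero_by_group(h2, rep("L5", 10), rep("s1", 10))
  expect_equal(fr2["s1", "L5"], 0.3)
  # empty (sample, group) cells are NA, not 0
  fr3 <- fraction_nonzero_by_group(c(1, 0), c("L5", "WM"), c("s1", "s2"))
  expect_true(is.na(fr3["s1", "WM"]))
  mw <- mean_weight_by_group(h, grp, smp)
  expect_equal(mw["s2", "L5"], 2)
})
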