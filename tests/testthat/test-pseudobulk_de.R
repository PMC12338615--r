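make_assay <- function(counts, group, sample, donor = sample) {
  count_assay(counts, gene_ids = sprintf("g%02d", seq_len(nrow(counts))),
              obs_ids = sprintf("o%03d", seq_len(ncol(counts))),
              obs_meta = data.frame(group = group, sample = sample,
                                    donor = donor))
}

test_that("pseudobulking conserves counts and drops thin columns", {
  set.seed(20)
  counts <- matrix(rpois(10 * 35, 5), 10, 35)
  group <- rep(c("A", "B"), c(22, 13))
  sample <- rep(c("s1", "s2", "s1", "s2"), c(11, 11, 11, 2))
  a <- make_assay(counts, group, sample)
  pb <- pseudobulk(a, min_obs = 10, min_cpm = NULL)
  # the 2-spot (B, s2) cell is dropped and reported
  expect_equal(ncol(pb$counts), 3)
  expect_equal(pb$dropped_columns$n_obs, 2)
  # column totals equal hand sums of their member observations
  expect_equal(unname(pb$counts[, "A_s1"]), rowSums(counts[, 1:11]))
  expect_equal(unname(pb$counts[, "B_s1"]), rowSums(counts[, 23:33]))

  # merging two spots of counts (1,2) and (3,4) gives the column (4,6)
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  a2 <- make_assay(m, c("A", "A"), c("s", "s"))
  expect_error(pseudobulk(a2, min_obs = 1), "fewer than 2 groups")
  a3 <- make_assay(cbind(m, c(9, 9)), c("A", "A", "B"), c("s", "s", "s"))
  pb3 <- pseudobulk(a3, min_obs = 1, min_cpm = NULL)
  expect_equal(unname(pb3$counts[, "A_s"]), c(4, 6))
})

test_that("moderated t reduces to OLS at prior df 0 and matches limma", {
  set.seed(21)
  counts <- matrix(rnbinom(20 * 12, mu = 60, size = 5), 20, 12)
  a <- make_assay(counts, rep(c("A", "B", "C"), each = 4),
                  paste0("s", 1:12))
  pb <- pseudobulk(a, min_obs = 1, min_cpm = NULL)

  st0 <- enrichment_model(pb, covariates = character(), prior_df = 0)
  design <- cbind(1, pb$meta$group == "A")
  ols_t <- apply(pb$logexpr, 1, function(y) {
    f <- lm.fit(design, y)
    s2 <- sum(f$residuals^2) / f$df.residual
    f$coefficients[2] / sqrt(s2 * solve(crossprod(design))[2, 2])
  })
  expect_lt(max(abs(st0$t[st0$group == "A"] - ols_t)), 1e-10)

  skip_if_not_installed("limma")
  st <- enrichment_model(pb, covariates = character())
  fit <- limma::eBayes(limma::lmFit(pb$logexpr, design))
  expect_lt(max(abs(st$t[st$group == "A"] - fit$t[, 2])), 1e-8)
  expect_lt(max(abs(st$p[st$group == "A"] - fit$p.value[, 2])), 1e-8)
})

test_that("genes with identical group means give null statistics", {
  set.seed(22)
  base <- matrix(rnbinom(15 * 4, mu = 40, size = 10), 15, 4)
  counts <- cbind(base, base)   # group B duplicates group A exactly
  a <- make_assay(counts, rep(c("A", "B"), each = 4), paste0("s", c(1:4, 1:4)))
  pb <- pseudobulk(a, min_obs = 1, min_cpm = NULL)
  st <- pairwise_model(pb, "A", "B")
  expect_equal(max(abs(st$logFC)), 0)
  expect_equal(max(abs(st$t)), 0)
  expect_equal(min(st$p), 1)
})

test_that("pairwise model is antisymmetric and matches one-vs-rest at 2 groups", {
  set.seed(23)
  counts <- matrix(rnbinom(30 * 8, mu = 50, size = 5), 30, 8)
  a <- make_assay(counts, rep(c("A", "B"), each = 4), paste0("s", 1:8))
  pb <- pseudobulk(a, min_obs = 1, min_cpm = NULL)
  ab <- pairwise_model(pb, "A", "B")
  ba <- pairwise_model(pb, "B", "A")
  expect_equal(ab$logFC, -ba$logFC)
  expect_equal(ab$t, -ba$t)
  enr <- enrichment_model(pb, covariates = character())
  expect_equal(ab$t, enr$t[enr$group == "A"], tolerance = 1e-10)
  expect_equal(ab$logFC, enr$logFC[enr$group == "A"], tolerance = 1e-10)
})

test_that("a confounded covariate raises a collinearity error", {
  set.seed(24)
  counts <- matrix(rpois(10 * 6, 30), 10, 6)
  a <- make_assay(counts, rep(c("A", "B"), each = 3), paste0("s", 1:6),
                  donor = rep(c("d1", "d2"), each = 3))
  pb <- pseudobulk(a, min_obs = 1, min_cpm = NULL)
  expect_error(enrichment_model(pb, covariates = "donor"), "singular design")
})

test_that("significance requires both cut-offs; top markers rank by t", {
  st <- data.frame(gene = c("a", "b", "c"), group = "G",
                   logFC = c(1.4, 1.6, 2.0), t = c(5, 4, 3),
                   p = c(0.001, 0.001, 0.5), fdr = c(0.04, 0.04, 0.2))
  sg <- significant_genes(st, lfc_cut = 1.5, alpha = 0.05)
  expect_identical(sg$significant, c(FALSE, TRUE, FALSE))
  tm <- top_markers(st, 2)
  expect_identical(tm$gene, c("a", "b"))
  expect_warning(top_markers(st, 5), "full ranking")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- (n / seq_len(n)) * p[o]
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(25)
  for (i in 1:50) {
    p <- runif(sample(5:1000, 1))^sample(c(1, 2, 0.5), 1)
    expect_identical(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("planted markers are recovered with small bias across simulations", {
  sim <- sim_default()
  st <- stats_default()$spatial_A
  # a planted L2 marker has true one-vs-rest logFC = marker_lfc at 10 donors
  l2 <- sim$truth$marker_sets$L2
  sub <- st[st$group == "L2" & st$gene %in% l2, ]
  expect_lt(abs(mean(sub$logFC) - sim$truth$config$marker_lfc), 0.3)
  # the typical marker is called confidently; only the weakest-expressed
  # markers (gamma base rates near the floor) can miss the FDR cut
  expect_lt(median(sub$fdr), 0.01)
  expect_gte(mean(sub$fdr < 0.01), 0.8)

  # mean bias over 20 small simulated datasets stays below 0.1 (capture
  # areas large enough that pseudobulk columns escape small-count
  # compression of log2(CPM + 1))
  biases <- vapply(1:20, function(s) {
    si <- simulate_paired_regions(sim_config(
      n_donors = 3, n_genes = 600, markers_per_layer = 40, flat_genes = 100,
      n_nuclei_per_donor = 60, spots_per_band = 60, seed = 100 + s
    ))
    aA <- merge_region(si$spatial$A)
    pb <- pseudobulk(aA, group_key = "band", sample_key = "sample",
                     min_obs = 5)
    st_i <- enrichment_model(pb)
    mk <- si$truth$marker_sets$L3
    mean(st_i$logFC[st_i$group == "L3" & st_i$gene %in% mk]) -
      si$truth$config$marker_lfc
  }, numeric(1))
  expect_lt(abs(mean(biases)), 0.1)
})

test_that("enrichment t-statistics ignore column order", {
  set.seed(26)
  counts <- matrix(rnbinom(20 * 9, mu = 45, size = 5), 20, 9)
  a <- make_assay(counts, rep(c("A", "B", "C"), 3), paste0("s", 1:9))
  pb1 <- pseudobulk(a, min_obs = 1, min_cpm = NULL)
  perm <- sample(9)
  a2 <- subset_assay(a, obs = perm)
  pb2 <- pseudobulk(a2, min_obs = 1, min_cpm = NULL)
  s1 <- enrichment_model(pb1, covariates = character())
  s2 <- enrichment_model(pb2, covariates = character())
  expect_equal(s1$t, s2$t, tolerance = 1e-12)
})
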