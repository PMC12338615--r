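fake_pb <- function(counts, group, donor) {
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  structure(list(counts = counts, logexpr = log2(cpm + 1),
                 meta = data.frame(group = group,
                                   sample = paste0(donor, "_", group),
                                   donor = donor, n_obs = 50)),
            class = "pseudobulk")
}

test_that("combining pseudobulks intersects genes and requires shared donors", {
  set.seed(50)
  cts <- matrix(rpois(100 * 8, 40), 100, 8,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  pa <- fake_pb(cts, rep(c("L1", "L5"), 4), rep(paste0("d", 1:4), each = 2))
  cts_b <- cts[1:60, ] + matrix(rpois(60 * 8, 5), 60)
  pb_ <- fake_pb(cts_b, rep(c("L1", "L5"), 4), rep(paste0("d", 1:4), each = 2))
  cpb <- combine_pseudobulks(pa, pb_)
  expect_equal(nrow(cpb$logexpr), 60)
  expect_setequal(unique(cpb$meta$Layer_Tissue),
                  c("L1_A", "L5_A", "L1_B", "L5_B"))

  # disjoint gene sets
  pb2 <- pb_
  rownames(pb2$counts) <- paste0("x", 1:60)
  expect_error(combine_pseudobulks(pa, pb2), "share no genes")

  # disjoint donors
  pb3 <- pb_
  pb3$meta$donor <- paste0("e", 1:8)
  expect_error(combine_pseudobulks(pa, pb3), "no shared donors")
})

test_that("identical matrices relabelled as two tissues give null contrasts", {
  set.seed(51)
  cts <- matrix(rpois(80 * 6, 60), 80, 6,
                dimnames = list(sprintf("g%02d", 1:80), NULL))
  pa <- fake_pb(cts, rep("L5", 6), paste0("d", 1:6))
  pb_ <- fake_pb(cts, rep("L5", 6), paste0("d", 1:6))
  cpb <- combine_pseudobulks(pa, pb_)
  res <- mixed_model_contrast(cpb, "L5_A", "L5_B")
  expect_equal(max(abs(res$logFC)), 0)
  expect_equal(min(res$p), 1)
  expect_equal(count_degs(res), 0)
})

test_that("the forced-OLS fit matches the closed-form OLS z-scores", {
  set.seed(52)
  n_donor <- 6
  LT <- rep(c("L5_A", "L5_B"), n_donor)
  donor <- rep(paste0("d", 1:n_donor), each = 2)
  Y <- matrix(rnorm(40 * length(LT), mean = 8), 40,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  Y[1:5, LT == "L5_A"] <- Y[1:5, LT == "L5_A"] + 2
  cpb <- structure(list(logexpr = Y,
                        meta = data.frame(Layer_Tissue = LT, Donor = donor)),
                   class = "combined_pseudobulk")
  res <- mixed_model_contrast(cpb, "L5_A", "L5_B", lambda = 0)
  X <- stats::model.matrix(~ 0 + factor(LT))
  cv <- c(1, -1)
  ols_z <- apply(Y, 1, function(y) {
    f <- lm.fit(X, y)
    s2 <- sum(f$residuals^2) / f$df.residual
    sum(cv * f$coefficients) /
      sqrt(s2 * drop(t(cv) %*% solve(crossprod(X)) %*% cv))
  })
  expect_lt(max(abs(abs(res$z) - abs(ols_z))), 1e-6)
  expect_equal(sign(res$z), unname(sign(ols_z)))
})

test_that("the REML fit agrees with lmer on data with real donor variance", {
  skip_if_not_installed("lmerTest")
  set.seed(53)
  n_donor <- 8
  meta <- expand.grid(Layer = c("L1", "L5"), Tissue = c("A", "B"),
                      Donor = sprintf("d%d", 1:n_donor))
  LT <- paste0(meta$Layer, "_", meta$Tissue)
  Y <- t(vapply(1:15, function(g) {
    de <- rnorm(n_donor, 0, 0.7)
    0.5 * (LT == "L5_A") + de[as.integer(factor(meta$Donor))] +
      rnorm(nrow(meta), 0, 0.4)
  }, numeric(nrow(meta))))
  rownames(Y) <- sprintf("g%02d", 1:15)
  cpb <- structure(list(logexpr = Y,
                        meta = data.frame(Layer_Tissue = LT,
                                          Donor = meta$Donor)),
                   class = "combined_pseudobulk")
  ours <- mixed_model_contrast(cpb, "L5_A", "L5_B")
  ref <- vapply(1:15, function(g) {
    d <- data.frame(y = Y[g, ], LT = LT, Donor = meta$Donor)
    m <- lmerTest::lmer(y ~ 0 + LT + (1 | Donor), data = d, REML = TRUE)
    b <- lme4::fixef(m)
    vc <- as.matrix(stats::vcov(m))
    i <- match(c("LTL5_A", "LTL5_B"), names(b))
    est <- b[i[1]] - b[i[2]]
    se <- sqrt(vc[i[1], i[1]] + vc[i[2], i[2]] - 2 * vc[i[1], i[2]])
    c(est, est / se)
  }, numeric(2))
  expect_lt(max(abs(ours$logFC - ref[1, ])), 1e-6)
  expect_lt(max(abs(abs(ours$z) - abs(ref[2, ]))), 1e-5)
})

test_that("the random intercept buys power when donors differ strongly", {
  set.seed(54)
  n_donor <- 6
  meta <- expand.grid(Tissue = c("A", "B"), Donor = sprintf("d%d", 1:n_donor))
  LT <- paste0("L5_", meta$Tissue)
  wins <- vapply(1:20, function(i) {
    de <- rnorm(n_donor, 0, 2)
    y <- 0.8 * (meta$Tissue == "A") +
      de[as.integer(factor(meta$Donor))] + rnorm(nrow(meta), 0, 0.3)
    cpb <- structure(list(logexpr = matrix(y, 1, dimnames = list("g1", NULL)),
                          meta = data.frame(Layer_Tissue = LT,
                                            Donor = meta$Donor)),
                     class = "combined_pseudobulk")
    r <- mixed_model_contrast(cpb, "L5_A", "L5_B")
    naive <- stats::t.test(y[meta$Tissue == "A"], y[meta$Tissue == "B"])
    c(mixed = abs(r$z) > 1.96, naive = unname(abs(naive$statistic)) > 2.228)
  }, logical(2))
  expect_gt(mean(wins["mixed", ]), mean(wins["naive", ]))
})

test_that("DEG counting applies strict joint thresholds on a known fixture", {
  # 50 genes; by construction exactly 7 satisfy |z| > 1.645 AND |logFC| > 1.5
  fx <- data.frame(
    gene = sprintf("g%02d", 1:50),
    logFC = c(rep(2.0, 5), -1.8, 1.7,            # 7 qualifying
              1.4, 2.0, 2.0, 1.5,                # fail one rule each
              rep(0.2, 39)),
    z = c(rep(3.0, 5), -2.1, 1.9,
          2.5, 1.645, -1.0, 4.0,
          rep(0.3, 39))
  )
  # independent enumeration
  manual <- sum(vapply(seq_len(50), function(i) {
    abs(fx$z[i]) > 1.645 && abs(fx$logFC[i]) > 1.5
  }, logical(1)))
  expect_equal(manual, 7)
  expect_equal(count_degs(fx), 7)
  # boundary rows are excluded: z exactly 1.645, |logFC| exactly 1.5
  expect_equal(count_degs(fx[9, ]), 0)
  expect_equal(count_degs(fx[11, ]), 0)
  expect_equal(count_degs(fx[8, ]), 0)   # z passes, logFC 1.4 fails
})

test_that("the DEG matrix transposes when tissue labels swap", {
  set.seed(55)
  sim <- sim_small()
  aA <- merge_region(sim$spatial$A)
  aB <- merge_region(sim$spatial$B)
  pbA <- pseudobulk(aA, group_key = "band", sample_key = "sample",
                    min_obs = 5, min_cpm = NULL)
  pbB <- pseudobulk(aB, group_key = "band", sample_key = "sample",
                    min_obs = 5, min_cpm = NULL)
  la <- c("L5", "WM")
  lb <- c("L4", "L5")
  cpb <- combine_pseudobulks(pbA, pbB)
  m1 <- deg_count_matrix(cpb, layers_a = la, layers_b = lb)
  cpb_sw <- combine_pseudobulks(pbB, pbA)
  m2 <- deg_count_matrix(cpb_sw, layers_a = lb, layers_b = la)
  expect_equal(m1$raw, t(m2$raw))
  # scaled rows sum to 1 where the row total is positive
  rs <- rowSums(m1$scaled)
  expect_true(all(abs(rs[rowSums(m1$raw) > 0] - 1) < 1e-12))
})

test_that("logFC concordance classifies enrichment categories", {
  sa <- data.frame(gene = c("g1", "g2"), group = "L5", logFC = c(1.3, 1.0))
  sb <- data.frame(gene = c("g1", "g2"), group = "L5", logFC = c(1.0, 1.3))
  cc <- logfc_concordance(sa, sb, "L5", "L5")
  expect_identical(cc$table$category, c("A_enriched", "B_enriched"))

  # identical stats: no exclusive categories, r = 1
  cc2 <- logfc_concordance(sa, sa, "L5", "L5")
  expect_false(any(cc2$table$category %in% c("A_enriched", "B_enriched")))
  expect_equal(cc2$r, 1)

  # region-A-private markers land in A_enriched on synthetic data
  sim <- sim_small()
  aA <- merge_region(sim$spatial$A)
  aB <- merge_region(sim$spatial$B)
  stA <- enrichment_model(pseudobulk(aA, group_key = "band",
                                     sample_key = "sample", min_obs = 5,
                                     min_cpm = NULL))
  stB <- enrichment_model(pseudobulk(aB, group_key = "band",
                                     sample_key = "sample", min_obs = 5,
                                     min_cpm = NULL))
  cc3 <- logfc_concordance(stA, stB, "L5", "L5")
  rare <- cc3$table[cc3$table$gene %in% sim$truth$marker_sets$rare, ]
  expect_gt(mean(rare$category == "A_enriched"), 0.9)
  shared <- cc3$table[cc3$table$gene %in% sim$truth$marker_sets$L5, ]
  expect_gte(mean(shared$category == "both"), 0.75)
})
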