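test_that("signature sets use strict thresholds and the local universe", {
  tab <- data.frame(
    gene = paste0("g", 1:10),
    logFC = c(2, 1, -1, 0, 0.5, -2, 3, -0.5, 1, -1),
    adj_p = c(0.01, 0.05, 0.02, 0.01, 0.1, 0.2, 0.09, 0.01, 0.5, 0.15)
  )
  ss <- build_signature_sets(tab, local_genes = tab$gene, alpha = 0.1)
  # strict <: adj_p exactly 0.1 goes to background; logFC 0 is neither sign
  expect_setequal(ss$up, c("g1", "g2", "g7"))
  expect_setequal(ss$down, c("g3", "g8"))
  expect_true(all(c("g4", "g5") %in% ss$background))
  expect_equal(length(ss$up) + length(ss$down) + length(ss$background), 10)

  # universe restricted to the overlap
  ss2 <- build_signature_sets(tab, local_genes = paste0("g", 1:5))
  expect_setequal(ss2$universe, paste0("g", 1:5))
  expect_error(build_signature_sets(tab, local_genes = "zz"), "no overlap")
})

test_that("domain sets apply their strict FDR and logFC rules", {
  st <- data.frame(
    gene = rep(paste0("g", 1:6), 2),
    group = rep(c("L1", "L2"), each = 6),
    logFC = c(2, 1, 1.5, 3, 0.5, -2, rep(0.1, 6)),
    fdr = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01, rep(0.9, 6))
  )
  ds <- build_domain_sets(st, alpha = 0.05, lfc = 1)
  # logFC exactly 1 is excluded; FDR 0.2 is excluded; negative excluded
  expect_setequal(ds$L1$set, c("g1", "g3"))
  expect_equal(length(ds$L1$set) + length(ds$L1$background), 6)
  # a domain with no qualifying genes carries a note
  expect_identical(ds$L2$set, character(0))
  expect_match(ds$L2$note, "empty")
})

test_that("Fisher's exact test matches closed forms and the enumeration oracle", {
  u <- paste0("g", 1:20)
  # balanced independent table: OR 1, p 1
  ft <- fisher_test(u[1:10], u[c(1:5, 11:15)], u)
  expect_equal(ft$odds_ratio, 1)
  expect_equal(ft$p, 1)

  # perfectly concordant disjoint table (10,0;0,10)
  ft2 <- fisher_test(u[1:10], u[1:10], u)
  expect_equal(ft2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(ft2$p, 1.0825e-5, tolerance = 1e-3)

  # two-sided enumeration oracle over all tables with fixed margins
  fisher_oracle <- function(a, b, cc, d) {
    m <- a + b; n <- cc + d; k <- a + cc
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    obs <- dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(70)
  for (i in 1:30) {
    tot <- sample(10:30, 1)
    uu <- paste0("x", seq_len(tot))
    sa <- sample(uu, sample(1:(tot - 1), 1))
    sb <- sample(uu, sample(1:(tot - 1), 1))
    a <- length(intersect(sa, sb)); b <- length(setdiff(sa, sb))
    cc <- length(setdiff(sb, sa)); d <- tot - a - b - cc
    ft_i <- fisher_test(sa, sb, uu)
    expect_equal(ft_i$p, fisher_oracle(a, b, cc, d), tolerance = 1e-12)
    # transpose symmetry
    expect_equal(fisher_test(sb, sa, uu)$p, ft_i$p, tolerance = 1e-12)
  }

  # degenerate margins are skipped with a note
  ft3 <- fisher_test(character(0), u[1:5], u)
  expect_true(ft3$skipped)
  expect_error(fisher_test(c("zz"), u[1:5], u), "subsets")
})

test_that("diluting a signature with independent genes pulls the OR toward 1", {
  set.seed(71)
  u <- paste0("g", 1:2000)
  dom <- u[1:200]
  core <- u[1:80]                      # strongly enriched core
  ors <- vapply(c(0, 400, 1600), function(extra) {
    sig <- c(core, sample(setdiff(u, core), extra))
    fisher_test(dom, sig, u)$odds_ratio
  }, numeric(1))
  expect_true(all(diff(ors) < 0))
  expect_gt(ors[1], ors[3] * 2)
})

test_that("enrichment families are tested and BH-adjusted together", {
  set.seed(72)
  st <- data.frame(
    gene = rep(paste0("g", 1:100), 2),
    group = rep(c("L1", "L2"), each = 100),
    logFC = c(c(rep(3, 20), rnorm(80, 0, 0.3)), rnorm(100, 0, 0.3)),
    fdr = c(c(rep(0.001, 20), runif(80, 0.2, 1)), runif(100, 0.2, 1))
  )
  ds <- build_domain_sets(st)
  ext <- data.frame(gene = paste0("g", 1:100),
                    logFC = c(rep(1, 25), rep(-1, 25), rep(0.1, 50)),
                    adj_p = c(rep(0.01, 50), runif(50, 0.3, 1)))
  ss <- build_signature_sets(ext, local_genes = paste0("g", 1:100))
  res <- run_enrichment(ds, ss)
  expect_equal(nrow(res), 4)
  expect_true(all(res$fdr[!res$skipped] >= res$p[!res$skipped] - 1e-12))
  # the L1 set overlaps the "up" signature (both built from g1..g20/25)
  expect_lt(res$p[res$domain == "L1" & res$signature == "up"], 0.05)
})

test_that("ortholog mapping keeps one-to-one rows and reports drops", {
  map <- data.frame(from = c("m1", "m2", "m3", "m4", "m4"),
                    to = c("H1", "H2", "H2", "H4", "H5"))
  om <- ortholog_map(c("m1", "m2", "m3", "m4", "m9"), map)
  # m2/m3 share a target, m4 maps twice: all dropped without priority
  expect_identical(om$mapped$from, "m1")
  expect_equal(unname(om$dropped["unmatched"]), 1)
  expect_equal(unname(om$dropped["ambiguous"]), 3)

  # a priority column resolves one-to-many
  map2 <- data.frame(from = c("m4", "m4"), to = c("H4", "H5"),
                     priority = c(2, 1))
  om2 <- ortholog_map("m4", map2)
  expect_identical(om2$mapped$to, "H4")

  # empty mapping drops everything
  om3 <- ortholog_map(c("a", "b"), map[0, ])
  expect_equal(nrow(om3$mapped), 0)
  expect_equal(unname(om3$dropped["unmatched"]), 2)
})

test_that("specificity annotations take the top decile and clip windows", {
  set.seed(73)
  counts <- matrix(rpois(100 * 4, 50), 100, 4,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  counts[1:10, 1:2] <- counts[1:10, 1:2] + 500    # domain-1 favourites
  pb <- structure(list(
    counts = counts,
    logexpr = log2(t(t(counts) / colSums(counts)) * 1e6 + 1),
    meta = data.frame(group = rep(c("L1", "L2"), each = 2),
                      sample = paste0("s", 1:4), donor = paste0("d", 1:4),
                      n_obs = c(60, 60, 60, 20))
  ), class = "pseudobulk")
  coords <- data.frame(gene = rownames(counts), chrom = "chr1",
                       start = seq(40e3, by = 50e3, length.out = 100),
                       end = seq(60e3, by = 50e3, length.out = 100),
                       biotype = rep(c("protein_coding", "lincRNA"),
                                     c(90, 10)))
  beds <- specificity_annotation(pb, coords, top_frac = 0.10, window = 1e5,
                                 min_obs = 50)
  # the 20-spot column is dropped, leaving both groups; 90 coding genes
  # -> 9 per set
  expect_equal(nrow(beds$L1), 9)
  expect_true(all(beds$L1$gene %in% sprintf("g%03d", 1:10)))
  # first gene starts at 40kb: window clips at 0
  g1 <- beds$L1[beds$L1$gene == "g001", ]
  expect_equal(g1$start, 0)
  expect_equal(g1$end, 60e3 + 1e5)

  # BED round-trips through a plain interval reader
  d <- withr::local_tempdir()
  paths <- write_bed(beds, d)
  back <- utils::read.table(paths[["L1"]], sep = "\t")
  expect_equal(back$V2, beds$L1$start)
  expect_equal(back$V3, beds$L1$end)
  expect_equal(back$V4, beds$L1$gene)
})
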