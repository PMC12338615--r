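# Shared fixtures, memoised so expensive simulations and fits are computed
# once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, expr, envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small paired dataset for module-level tests
sim_small <- function() {
  memo("sim_small", simulate_paired_regions(sim_config(
    n_donors = 3, n_genes = 600, markers_per_layer = 40, flat_genes = 100,
    n_nuclei_per_donor = 200, seed = 3
  )))
}

# the default study conditions (used by the recovery criteria)
sim_default <- function() {
  memo("sim_default", simulate_paired_regions(sim_config()))
}

# concatenate one region's capture areas into a single assay
merge_region <- function(samples) {
  a1 <- samples[[1]]$assay
  count_assay(
    do.call(cbind, lapply(samples, function(x) x$assay$counts)),
    gene_ids = a1$gene_ids,
    obs_ids = unlist(lapply(samples, function(x) x$assay$obs_ids)),
    gene_meta = a1$gene_meta,
    obs_meta = do.call(rbind, lapply(samples, function(x) x$assay$obs_meta))
  )
}

# enrichment statistics for the default dataset (both modalities)
stats_default <- function() {
  memo("stats_default", {
    sim <- sim_default()
    aA <- merge_region(sim$spatial$A)
    pbA <- pseudobulk(aA, group_key = "band", sample_key = "sample")
    pbN <- pseudobulk(sim$nuclei, group_key = "cell_type",
                      sample_key = "sample")
    list(spatial_A = enrichment_model(pbA),
         nuclei = enrichment_model(pbN))
  })
}

# NMF of the default nuclei (rank chosen as roughly four patterns per cell
# type, mirroring how overcomplete factorizations isolate rare programs)
nmf_default <- function() {
  memo("nmf_default", {
    sim <- sim_default()
    mod <- nmf_fit(log_normalize(sim$nuclei), k = 32, seed = 42,
                   max_iter = 300, tol = 1e-6)
    qc <- compute_qc(sim$nuclei)
    tf <- technical_filter(mod, data.frame(
      sum = qc$sum, detected = qc$detected, mito_pct = qc$mito_pct,
      donor = sim$nuclei$obs_meta$donor, sex = sim$nuclei$obs_meta$sex
    ))
    ann <- annotate_patterns(mod, sim$nuclei$obs_meta$cell_type,
                             technical = tf$technical)
    list(model = mod, technical = tf, annotation = ann)
  })
}

# pattern weights projected into every capture area of both regions
proj_default <- function() {
  memo("proj_default", {
    sim <- sim_default()
    mod <- nmf_default()$model
    lapply(sim$spatial, function(region) {
      lapply(region, function(s) {
        project_patterns(mod, log_normalize(s$assay))$H_new
      })
    })
  })
}

# hand-enumerable 10-spot capture area: 1 out-of-tissue, 1 all-zero,
# 1 low-detected, 1 low-sum, and 6 clean spots
spot_fixture <- function() {
  set.seed(99)
  n_genes <- 60
  counts <- matrix(rpois(n_genes * 10, 5), n_genes, 10)
  counts[, 2] <- 0                                   # all zero
  counts[, 3] <- c(rep(1, 19), rep(0, n_genes - 19)) # 19 detected, sum 19
  counts[, 4] <- c(rep(30, 10), rep(0, n_genes - 10)) # detected 10, sum 300
  gene_meta <- data.frame(mito = rep(c(TRUE, FALSE), c(3, n_genes - 3)))
  assay <- count_assay(counts, gene_ids = sprintf("g%02d", 1:n_genes),
                       obs_ids = sprintf("s%02d", 1:10),
                       gene_meta = gene_meta)
  spatial_sample(assay, xy = cbind(1:10, 1), in_tissue = c(FALSE, rep(TRUE, 9)),
                 sample_id = "fx", donor = "d1")
}
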