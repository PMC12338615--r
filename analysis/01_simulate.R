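#!/usr/bin/env Rscript
# Generate the paired-region study data: SRT capture areas for the agranular
# region A and granular region B in ten donors, matched single-nucleus pools,
# and an smFISH cell table. Writes 10x-dialect files for one capture area so
# the readers can be exercised end to end, plus ground-truth tables.

library(cortexpair)

dir.create("results", showWarnings = FALSE)
sim <- simulate_paired_regions(sim_config())

cat(sprintf(
  "simulated %d donors: %d region-A areas, %d region-B areas, %d nuclei\n",
  sim$truth$config$n_donors, length(sim$spatial$A), length(sim$spatial$B),
  ncol(sim$nuclei$counts)
))

# one capture area in SpaceRanger-style files (readable by read_10x_mtx)
s1 <- sim$spatial$A[[1]]
write_10x_mtx(s1$assay, "results/sim_A_d01_10x")
write_tsv(data.frame(
  barcode = s1$assay$obs_ids, in_tissue = as.integer(s1$in_tissue),
  array_row = s1$xy[, "y"], array_col = s1$xy[, "x"],
  pxl_row_in_fullres = s1$xy[, "y"], pxl_col_in_fullres = s1$xy[, "x"]
), "results/sim_A_d01_positions.tsv")

# ground truth: marker programs and nucleus types
write_tsv(data.frame(
  program = rep(names(sim$truth$marker_sets),
                lengths(sim$truth$marker_sets)),
  gene = unlist(sim$truth$marker_sets)
), "results/truth_marker_sets.tsv")
write_tsv(sim$nuclei$obs_meta, "results/truth_nuclei_meta.tsv")

sm <- simulate_smfish(seed = sim$truth$config$seed)
write_tsv(sm$cells, "results/smfish_cells.tsv")
cat(sprintf("smFISH table: %d cells, genes %s (anchor %s)\n",
            nrow(sm$cells), paste(sm$truth$genes, collapse = ", "),
            sm$truth$anchor_gene))
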