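#!/usr/bin/env Rscript
# Spatially variable gene ranking per capture area with cross-sample rank
# aggregation, and cluster-validity metrics (neighbor purity, H+) of the
# true band labels in a null-residual PCA embedding.

library(cortexpair)

dir.create("results", showWarnings = FALSE)
sim <- simulate_paired_regions(sim_config())

svgs <- lapply(c(sim$spatial$A, sim$spatial$B), function(s) {
  spatial_variability_score(per_sample_gene_filter(filter_spots(s)),
                            k_neighbors = 6)
})
agg <- aggregate_svg(svgs, top_cut = 500, min_samples = 2)
write_tsv(agg, "results/svg_aggregate.tsv")
mk <- unlist(sim$truth$band_marker_sets)
cat(sprintf(
  "replicated SVGs: %d; planted band markers replicated: %.1f%%; flat genes: %.1f%%\n",
  sum(agg$replicated), 100 * mean(mk %in% agg$gene[agg$replicated]),
  100 * mean(sim$truth$flat_genes %in% agg$gene[agg$replicated])
))

# validity metrics of the band labels in a residual-PCA embedding
s <- filter_spots(sim$spatial$A[[1]])
pcs <- prcomp(t(null_pearson_residuals(s$assay)), rank. = 10)$x
pur <- neighbor_purity(pcs, s$domain, k = 25)
hp <- h_plus(pcs, s$domain, n_pairs = 1e5, seed = 1)
write_tsv(pur$per_cluster, "results/cluster_purity.tsv")
cat(sprintf("band-label purity %.3f, H+ %.3f (exact: %s)\n",
            pur$mean, hp$h_plus, hp$exact))
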