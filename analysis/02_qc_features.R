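#!/usr/bin/env Rscript
# Spot and nucleus quality control: hard count filters for the capture
# areas, MAD flags for reporting, barcode-rank knee demonstration, and
# Poisson-deviance feature selection for the nuclei.

library(cortexpair)

dir.create("results", showWarnings = FALSE)
sim <- simulate_paired_regions(sim_config())

reports <- list()
for (region in names(sim$spatial)) {
  for (s in sim$spatial[[region]]) {
    f <- filter_spots(s)
    rep_ <- attr(f, "filter_report")
    rep_$sample <- s$sample_id
    rep_$retained <- ncol(f$assay$counts)
    reports[[s$sample_id]] <- rep_
    qc <- compute_qc(s$assay)
    rep_$mad_low_sum <- sum(mad_outlier(qc$sum, side = "lower",
                                        log_transform = TRUE))
  }
}
filter_report <- do.call(rbind, reports)
write_tsv(filter_report, "results/qc_spot_filter_report.tsv")
cat(sprintf("spot filter: %d spots retained across %d capture areas\n",
            sum(filter_report$retained[!duplicated(filter_report$sample)]),
            length(reports)))

# barcode-rank knee on the nuclei totals plus planted empty droplets
qc_n <- compute_qc(sim$nuclei)
set.seed(1)
ambient <- round(rlnorm(20000, log(15), 0.5))
kt <- knee_threshold(c(qc_n$sum, ambient))
cat(sprintf("barcode-rank knee at %d UMIs (cliff %d); %d of %d nuclei above\n",
            kt$knee, kt$cliff, sum(qc_n$sum >= kt$knee), nrow(qc_n)))

dev <- poisson_deviance_selection(sim$nuclei, n_top = 2000)
write_tsv(dev, "results/qc_deviance_ranking.tsv")
mk <- unlist(sim$truth$marker_sets)
cat(sprintf("top-500 deviance genes containing planted markers: %.1f%%\n",
            100 * mean(dev$gene[1:500] %in% mk)))
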