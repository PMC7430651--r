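#!/usr/bin/env Rscript
# Stage 4 — abundance quantification.
#
# Counts reads per circle group (quality >= 20; tandem-array groups without a
# quality filter), normalizes by median-of-ratios size factors, keeps circles
# detected in at least two samples, and summarizes profiles by PCA and
# Manhattan/average-linkage clustering. Spike-in plasmid reads give
# library-independent rDNA and Y' abundance ratios; the rDNA share of
# circle-derived reads is reported per sample.

suppressMessages(library(ecclineage))
sim <- readRDS("scratch/sim.rds")
g <- readRDS("scratch/groups.rds")
classed <- g$classed

cm <- count_matrix(classed, sim$alignments)
sf <- size_factors_median_of_ratios(cm)
write_tsv(data.frame(sample = names(sf), size_factor = sf),
          "results/size_factors.tsv")
recurrent <- recurrence_filter(cm)
cat("recurrent circles (detected in >= 2 samples):", nrow(recurrent),
    "of", nrow(cm), "\n")
logmat <- normalize_log10(recurrent, sf)
pr <- cluster_profiles(logmat)
write_tsv(data.frame(sample = rownames(pr$pca$x), round(pr$pca$x[, 1:3], 4)),
          "results/pca_scores.tsv")
dendrogram_newick(pr$col_hclust, "results/samples.nwk")
dendrogram_newick(pr$row_hclust, "results/circles.nwk")

aged <- sim$sheet$sample[sim$sheet$subpopulation == "aged"]
d <- as.matrix(dist(t(logmat), method = "manhattan"))
sep <- max(d[aged, aged]) < min(d[aged, setdiff(colnames(d), aged)])
cat("aged samples form their own cluster:", sep, "\n")

td <- sim$genome$tandem
rdna_iv <- list(contig = td$contig, start = td$start, end = td$end)
is_rdna <- classed$contig == td$contig & classed$start < td$end &
  classed$end > td$start
is_yp <- classed$contig == sim$genome$dispersed$contig[1] &
  classed$end > min(sim$genome$dispersed$start) &
  classed$start < max(sim$genome$dispersed$end)
plasmids <- sim$genome$contig_table$name[
  sim$genome$contig_table$region_class == "plasmid"]
spike <- spike_in_levels(sim$alignments, plasmids, rdna_iv,
                         sim$genome$dispersed, classed[!is_rdna & !is_yp, ])
spike$subpopulation <- sim$sheet$subpopulation[
  match(spike$sample, sim$sheet$sample)]
write_tsv(spike, "results/spike_in.tsv")
for (sub in c("young", "aged"))
  cat(sprintf("median spike-normalized rDNA ratio, %s: %.2f\n", sub,
              median(spike$rdna_ratio[spike$subpopulation == sub])))

rdna_pct <- vapply(sim$sheet$sample, function(s)
  rdna_fraction(sim$alignments[[s]], rdna_iv, classed[!is_rdna, ]),
  numeric(1))
write_tsv(data.frame(sample = names(rdna_pct), rdna_percent = rdna_pct),
          "results/rdna_percent.tsv")
cat("rDNA percentage of circle-derived reads per sample:\n")
print(round(rdna_pct, 2))
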