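#!/usr/bin/env Rscript
# Stage 3 — inheritance classification.
#
# Groups calls across samples (+/-300 bp for unique calls, +/-400 bp for
# repeat calls), assigns classes I-V from the per-population young/progeny/
# aged presence patterns (conflicts resolve upward, I > {II, III, IV} > V;
# same-order conflicts become ambiguous), re-checks class IV circles against
# unfiltered aged detection, and estimates the de novo circle formation rate
# per cell division.

suppressMessages(library(ecclineage))
sim <- readRDS("scratch/sim.rds")
calls <- readRDS("scratch/calls.rds")

grouping <- group_circles(calls)
classed <- classify_inheritance(grouping, sim$sheet)
presence <- attr(classed, "presence")
write_tsv(cbind(classed[, c("group_id", "contig", "start", "end", "mode",
                            "class")],
                as.data.frame(presence)), "results/groups.tsv")

cat("inheritance classes:\n")
print(table(classed$class))
young <- sim$sheet$sample[sim$sheet$subpopulation == "young"]
in_young <- rowSums(presence[, young, drop = FALSE]) > 0
keep <- in_young & classed$class != "ambiguous"
cat(sprintf("class IV share of young circles: %.2f%%\n",
            100 * sum(classed$class[keep] == "IV") / sum(keep)))

aged <- sim$sheet$sample[sim$sheet$subpopulation == "aged"]
rescue <- rescue_unfiltered_class4(classed[classed$class == "IV", ],
                                   sim$alignments[aged])
write_tsv(data.frame(group_id = classed$group_id[classed$class == "IV"],
                     rescued = rescue$rescued), "results/rescue.tsv")
cat(sprintf("class IV with zero aged read evidence: %.2f%% (%d/%d)\n",
            100 * rescue$fraction_no_evidence,
            rescue$n_class4 - rescue$n_rescued, rescue$n_class4))

pops <- unique(sim$sheet$population)
n_denovo <- vapply(pops, function(p) {
  smp <- sim$sheet$sample[sim$sheet$population == p &
                            sim$sheet$subpopulation == "aged"]
  sum(classed$class == "V" & rowSums(presence[, smp, drop = FALSE]) > 0)
}, numeric(1))
rates <- de_novo_rate(n_denovo, sim$cohort$design$n_cells_recovered)
write_tsv(data.frame(population = pops, n_denovo = n_denovo,
                     rate = rates$rate), "results/de_novo_rate.tsv")
cat(sprintf("de novo rate median %.3g per cell division (range %.3g-%.3g)\n",
            rates$median, rates$range[1], rates$range[2]))

saveRDS(list(classed = classed, presence = presence), "scratch/groups.rds")
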