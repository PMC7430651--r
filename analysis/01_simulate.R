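#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Builds the toy yeast-like genome (two unique chromosomes, an rDNA-like
# 20-unit tandem array, a chromosome end with six Y'-like repeat copies, four
# spike-in plasmids), plans the planted circle cohort (2 populations x
# young/progeny/aged; 93.75% of young circles are class IV; rDNA-like circle
# inflated 400x in aged samples) and simulates one coordinate-sorted
# alignment set per sample.

suppressMessages(library(ecclineage))
seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

genome <- build_toy_genome(seed = seed)
sheet <- make_sample_sheet(c("P1", "P2"))
cohort <- plan_circle_cohort(genome, default_cohort_design(), sheet,
                             seed = seed)
alignments <- simulate_cohort(genome, cohort, seed = seed)

write_genome_files(genome, "scratch/sim")
lens <- setNames(genome$contig_table$length, genome$contig_table$name)
for (s in names(alignments))
  write_sam(alignments[[s]], file.path("scratch/sim", paste0(s, ".sam")), lens)
write_tsv(cohort_truth_table(cohort), "results/truth.tsv")
saveRDS(list(genome = genome, cohort = cohort, alignments = alignments,
             sheet = sheet, seed = seed), "scratch/sim.rds")

tt <- cohort_truth_table(cohort)
cat("planted circles:", nrow(cohort$circles), "\n")
print(table(cohort$circles$class))
cat("simulated records per sample:\n")
print(vapply(alignments, nrow, integer(1)))
cat("truth table -> results/truth.tsv; SAM/FASTA -> scratch/sim/\n")
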