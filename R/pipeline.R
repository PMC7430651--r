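#' Default pipeline configuration
#'
#' All tunable thresholds with their defaults: detection support and coverage
#' cuts, reciprocal-merge fractions, classification tolerances,
#' quantification settings and the saturation grid.
#'
#' @param seed top-level seed; stage randomness derives from it via fixed
#'   offsets so stages can be re-run independently.
#' @param outdir output directory.
#' @return config list for [run_pipeline()].
#' @export
default_config <- function(seed = 1L, outdir = tempfile("eccrun")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    genome = list(),
    design = default_cohort_design(),
    populations = c("P1", "P2"),
    read_length = 100L,
    error_rate = 0.001,
    unique = list(min_support = 5L, min_coverage = 0.9, merge_frac = 0.5,
                  min_mapq = 20L),
    repeat_mode = list(min_ratio = 0.8, max_edit = 2L, min_support = 20L,
                       merge_frac = 0.8, min_coverage = 0.8),
    tol_unique = 300L, tol_repeat = 400L,
    min_mapq_count = 20L, pseudocount = 1, min_recurrence = 2L,
    n_divisions = 15,
    saturation_fractions = seq(0.05, 1, by = 0.05),
    write_sam = FALSE
  )
}

validate_config <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg)
  chk(config$unique$min_support >= 1, "unique min_support must be >= 1")
  chk(config$repeat_mode$min_support >= 1, "repeat min_support must be >= 1")
  chk(config$unique$min_coverage >= 0 && config$unique$min_coverage <= 1,
      "unique min_coverage must be in [0, 1]")
  chk(config$repeat_mode$min_coverage >= 0 && config$repeat_mode$min_coverage <= 1,
      "repeat min_coverage must be in [0, 1]")
  chk(config$unique$merge_frac > 0 && config$unique$merge_frac <= 1,
      "unique merge_frac must be in (0, 1]")
  chk(config$repeat_mode$merge_frac > 0 && config$repeat_mode$merge_frac <= 1,
      "repeat merge_frac must be in (0, 1]")
  chk(config$tol_unique >= 0 && config$tol_repeat >= 0,
      "tolerances must be >= 0")
  chk(config$min_recurrence >= 1, "min_recurrence must be >= 1")
  chk(all(config$saturation_fractions > 0 & config$saturation_fractions <= 1),
      "saturation fractions must be in (0, 1]")
  invisible(TRUE)
}

#' Run the full synthetic Circle-Seq analysis
#'
#' simulate -> detect (unique + repeat) -> classify -> rescue -> quantify ->
#' enrich -> saturate. Deterministic for a fixed config and seed. Tables are
#' written under `config$outdir` together with a machine-readable manifest.
#'
#' @param config list from [default_config()].
#' @param motifs optional data.frame (name, motif) of cis-element motifs;
#'   defaults to the motif set shipped with the package.
#' @return invisibly, a list with every intermediate product (genome, cohort,
#'   alignments, calls, groups, rescue, rates, counts, profiles, spike-in
#'   report, enrichment, saturation).
#' @export
run_pipeline <- function(config = default_config(), motifs = NULL) {
  validate_config(config)
  t_start <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[ecclineage] ", ...)
  timings <- c()
  counts <- c()
  tick <- function(stage, n) {
    timings[stage] <<- round(as.numeric(Sys.time() - t_start, units = "secs"), 2)
    counts[stage] <<- n
    log_stage(stage, ": ", n, " records")
  }

  # simulate
  genome <- do.call(build_toy_genome,
                    c(config$genome, list(seed = config$seed)))
  sheet <- make_sample_sheet(config$populations)
  cohort <- plan_circle_cohort(genome, config$design, sheet,
                               seed = config$seed)
  alignments <- simulate_cohort(genome, cohort,
                                read_length = config$read_length,
                                error_rate = config$error_rate,
                                seed = config$seed)
  truth <- cohort_truth_table(cohort)
  write_tsv(truth, file.path(config$outdir, "truth.tsv"))
  if (isTRUE(config$write_sam)) {
    lens <- stats::setNames(genome$contig_table$length,
                            genome$contig_table$name)
    for (s in names(alignments))
      write_sam(alignments[[s]], file.path(config$outdir,
                                           paste0(s, ".sam")), lens)
    write_genome_files(genome, config$outdir)
  }
  tick("simulate", sum(vapply(alignments, nrow, integer(1))))

  # detect
  calls <- do.call(rbind, lapply(sheet$sample, function(s)
    detect_circles(alignments[[s]], sample = s,
                   unique_params = config$unique,
                   repeat_params = config$repeat_mode)))
  write_calls_tsv(calls, file.path(config$outdir, "calls.tsv"))
  tick("detect", nrow(calls))

  # classify
  grouping <- group_circles(calls, config$tol_unique, config$tol_repeat)
  classed <- classify_inheritance(grouping, sheet)
  write_tsv(classed[, setdiff(names(classed), "per_population")],
            file.path(config$outdir, "groups.tsv"))
  aged_samples <- sheet$sample[sheet$subpopulation == "aged"]
  rescue <- rescue_unfiltered_class4(
    classed[classed$class == "IV", , drop = FALSE],
    alignments[aged_samples], config$tol_unique, config$tol_repeat)
  presence <- attr(classed, "presence")
  pops <- unique(sheet$population)
  n_denovo <- vapply(pops, function(p) {
    smp <- sheet$sample[sheet$population == p & sheet$subpopulation == "aged"]
    sum(classed$class == "V" &
          rowSums(presence[, smp, drop = FALSE]) > 0)
  }, numeric(1))
  rates <- de_novo_rate(n_denovo, config$design$n_cells_recovered,
                        config$n_divisions)
  tick("classify", nrow(classed))

  # quantify
  cm <- count_matrix(classed, alignments, min_mapq = config$min_mapq_count)
  sf <- size_factors_median_of_ratios(cm)
  recurrent <- recurrence_filter(cm, config$min_recurrence)
  logmat <- normalize_log10(recurrent, sf, config$pseudocount)
  profiles <- cluster_profiles(logmat)
  write_tsv(data.frame(sample = names(sf), size_factor = sf),
            file.path(config$outdir, "size_factors.tsv"))
  utils::write.table(cm, file.path(config$outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE)
  dendrogram_newick(profiles$col_hclust,
                    file.path(config$outdir, "samples.nwk"))

  td <- genome$tandem
  rdna_iv <- list(contig = td$contig, start = td$start, end = td$end)
  is_rdna <- classed$contig == td$contig &
    classed$start < td$end & classed$end > td$start
  is_yp <- classed$contig == genome$dispersed$contig[1] &
    classed$start < max(genome$dispersed$end) &
    classed$end > min(genome$dispersed$start)
  plasmid_names <- genome$contig_table$name[
    genome$contig_table$region_class == "plasmid"]
  spike <- spike_in_levels(alignments, plasmid_names, rdna_iv,
                           genome$dispersed,
                           classed[!is_rdna & !is_yp, , drop = FALSE],
                           min_mapq = config$min_mapq_count)
  spike$population <- sheet$population[match(spike$sample, sheet$sample)]
  spike$subpopulation <- sheet$subpopulation[match(spike$sample, sheet$sample)]
  write_tsv(spike, file.path(config$outdir, "spike_in.tsv"))
  rdna_pct <- vapply(sheet$sample, function(s)
    rdna_fraction(alignments[[s]], rdna_iv,
                  classed[!is_rdna, , drop = FALSE],
                  min_mapq = config$min_mapq_count), numeric(1))

  # normalized fold changes aged vs young per population, median across pops
  norm <- normalize_counts(cm, sf)
  lfc_by_pop <- vapply(pops, function(p) {
    a <- sheet$sample[sheet$population == p & sheet$subpopulation == "aged"]
    y <- sheet$sample[sheet$population == p & sheet$subpopulation == "young"]
    log_fold_change(rowMeans(norm[, a, drop = FALSE]),
                    rowMeans(norm[, y, drop = FALSE]), config$pseudocount)
  }, numeric(nrow(cm)))
  lfc_median <- apply(lfc_by_pop, 1, stats::median)
  tick("quantify", nrow(cm))

  # enrich
  if (is.null(motifs)) motifs <- default_motifs()
  keep <- classed$class %in% c("I", "II", "III", "IV")
  gk <- classed[keep, , drop = FALSE]
  feat_pres <- annotate_features(gk, genome$features)
  motif_pres <- matrix(FALSE, nrow(gk), nrow(motifs),
                       dimnames = list(gk$group_id, motifs$name))
  for (i in seq_len(nrow(gk))) {
    s <- genome_sequence(genome, gk$contig[i], gk$start[i],
                         min(gk$end[i],
                             genome$contig_table$length[
                               genome$contig_table$name == gk$contig[i]]))
    motif_pres[i, ] <- vapply(motifs$motif, scan_motif, logical(1),
                              sequence = s)
  }
  enrich <- enrichment_screen(gk$class, feat_pres, motif_pres,
                              lengths = gk$end - gk$start)
  write_tsv(enrich$results, file.path(config$outdir, "enrichment.tsv"))
  tick("enrich", nrow(enrich$results))

  # saturate: unique-mode detector on the first young sample
  ys <- sheet$sample[sheet$subpopulation == "young"][1]
  sat <- saturation_curve(
    alignments[[ys]],
    detector = function(a) call_unique_circles(
      extract_junction_evidence(a), a, sample = ys,
      min_support = config$unique$min_support,
      min_coverage = config$unique$min_coverage,
      merge_frac = config$unique$merge_frac),
    fractions = config$saturation_fractions, seed = config$seed + 1L)
  write_tsv(sat, file.path(config$outdir, "saturation.tsv"))
  tick("saturate", nrow(sat))

  pkg_version <- tryCatch(as.character(utils::packageVersion("ecclineage")),
                          error = function(e) "devel")
  manifest <- list(package = "ecclineage",
                   version = pkg_version,
                   seed = config$seed,
                   config = config[setdiff(names(config), "outdir")],
                   stage_records = as.list(counts),
                   stage_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genome = genome, cohort = cohort, alignments = alignments,
                 truth = truth, calls = calls, groups = classed,
                 presence = presence, rescue = rescue, rates = rates,
                 counts = cm, size_factors = sf, logmat = logmat,
                 profiles = profiles, spike = spike, rdna_pct = rdna_pct,
                 lfc_median = lfc_median, is_rdna = is_rdna, is_yprime = is_yp,
                 enrichment = enrich, saturation = sat, sheet = sheet))
}

#' Cis-element motif set shipped with the package
#'
#' Short exact-match motifs in the spirit of yeast cis-regulatory elements
#' (an ACS-like core among them). Synthetic stand-ins for a curated binding
#' site collection: the toy genome is random sequence, so motif hits are
#' baseline occurrences unless a motif is planted.
#'
#' @return data.frame with columns name, motif.
#' @export
default_motifs <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "ecclineage")
  if (nzchar(path))
    return(utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  # fallback when running from a source checkout
  data.frame(
    name = c("ACS_core", "ABF1", "RAP1", "REB1", "MCB", "SCB", "TATA",
             "GCR1", "STRE", "PDS"),
    motif = c("TTTATGTTTA", "TCACACGACG", "ACACCCATACAT", "TTACCCGG",
              "ACGCGT", "CACGAAAA", "TATAAA", "CTTCC", "CCCCT", "AGGGAT"),
    stringsAsFactors = FALSE)
}
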