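#' Build a toy yeast-like genome for Circle-Seq simulation
#'
#' Constructs a small genome with the region classes that matter for circular
#' DNA detection: uniquely mappable chromosomes, one rDNA-like tandem repeat
#' array (an integer number of near-identical unit copies, one replication
#' origin per unit), a chromosome end carrying dispersed Y'-like repeat copies,
#' and spike-in plasmid contigs. Feature annotations (origins, centromere,
#' LTRs, telomere, retrotransposon, introns, genes) are laid out so that
#' downstream enrichment tests have material to work with.
#'
#' All coordinates are 0-based half-open; conversion to 1-based happens only at
#' SAM/GFF write boundaries.
#'
#' @param unique_sizes named integer vector of unique-contig lengths (bases).
#' @param tandem_units number of repeat units in the tandem array.
#' @param tandem_unit_length length of one tandem repeat unit (bases).
#' @param tandem_flank unique flank on each side of the tandem array (bases).
#' @param dispersed_copies number of dispersed repeat copies (>= 2).
#' @param dispersed_copy_length length of one dispersed copy (bases).
#' @param dispersed_gap gap between consecutive dispersed copies (bases).
#' @param plasmids named integer vector of spike-in plasmid lengths.
#' @param divergence per-base substitution rate between repeat copies, in
#'   `[0, 0.1]`. 0 makes copies identical.
#' @param seed integer seed; the same (config, seed) gives a byte-identical
#'   genome.
#' @return an object of class `ecc_genome`: list with `contigs`
#'   (named [Biostrings::DNAStringSet]), `contig_table` (data.frame: name,
#'   length, region_class), `tandem` (list: contig, start, end, unit_length,
#'   n_units), `dispersed` (data.frame of copy intervals), and `features`
#'   (data.frame: kind, contig, start, end, name).
#' @export
build_toy_genome <- function(unique_sizes = c(chrU1 = 120000L, chrU2 = 100000L),
                             tandem_units = 20L,
                             tandem_unit_length = 1000L,
                             tandem_flank = 5000L,
                             dispersed_copies = 6L,
                             dispersed_copy_length = 1000L,
                             dispersed_gap = 50L,
                             plasmids = c(pUC19_yEGFP = 3000L, pSH63 = 3000L,
                                          p4339 = 3000L, pRS316 = 3000L),
                             divergence = 0.005,
                             seed = 1L) {
  if (divergence < 0 || divergence > 0.1)
    stop("divergence must be in [0, 0.1]")
  if (any(unique_sizes < 1000L) || any(plasmids < 1000L))
    stop("every contig must be at least 1 kb")
  if (tandem_units < 2L || tandem_unit_length < 100L)
    stop("tandem array needs >= 2 units of >= 100 bases")
  if (dispersed_copies < 2L)
    stop("need >= 2 dispersed repeat copies")

  withr_seed <- local_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  mutate_seq <- function(s, rate) {
    if (rate <= 0) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    if (length(hit)) {
      repl <- vapply(v[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1))
      v[hit] <- repl
    }
    paste(v, collapse = "")
  }

  seqs <- list()
  contig_rows <- list()
  for (nm in names(unique_sizes)) {
    seqs[[nm]] <- rand_seq(unique_sizes[[nm]])
    contig_rows[[nm]] <- data.frame(name = nm, length = unique_sizes[[nm]],
                                    region_class = "unique")
  }

  # rDNA-like contig: flank | units | flank
  unit <- rand_seq(tandem_unit_length)
  units <- vapply(seq_len(tandem_units),
                  function(i) if (i == 1L) unit else mutate_seq(unit, divergence),
                  character(1))
  tandem_contig <- "chrR"
  tandem_start <- tandem_flank
  tandem_end <- tandem_flank + tandem_units * tandem_unit_length
  seqs[[tandem_contig]] <- paste0(rand_seq(tandem_flank),
                                  paste(units, collapse = ""),
                                  rand_seq(tandem_flank))
  contig_rows[[tandem_contig]] <- data.frame(name = tandem_contig,
                                             length = nchar(seqs[[tandem_contig]]),
                                             region_class = "tandem_array")

  # chromosome end with dispersed Y'-like copies separated by unique spacers
  disp_contig <- "chrY"
  copy <- rand_seq(dispersed_copy_length)
  lead <- 12000L
  pieces <- list(rand_seq(lead))
  disp_rows <- list()
  pos <- lead
  for (i in seq_len(dispersed_copies)) {
    s <- if (i == 1L) copy else mutate_seq(copy, divergence)
    pieces[[length(pieces) + 1L]] <- s
    disp_rows[[i]] <- data.frame(contig = disp_contig, start = pos,
                                 end = pos + dispersed_copy_length)
    pos <- pos + dispersed_copy_length
    if (i < dispersed_copies) {
      pieces[[length(pieces) + 1L]] <- rand_seq(dispersed_gap)
      pos <- pos + dispersed_gap
    }
  }
  pieces[[length(pieces) + 1L]] <- rand_seq(1000L)
  seqs[[disp_contig]] <- paste(pieces, collapse = "")
  contig_rows[[disp_contig]] <- data.frame(name = disp_contig,
                                           length = nchar(seqs[[disp_contig]]),
                                           region_class = "dispersed_repeat")
  dispersed <- do.call(rbind, disp_rows)

  for (nm in names(plasmids)) {
    seqs[[nm]] <- rand_seq(plasmids[[nm]])
    contig_rows[[nm]] <- data.frame(name = nm, length = plasmids[[nm]],
                                    region_class = "plasmid")
  }

  contig_table <- do.call(rbind, contig_rows)
  rownames(contig_table) <- NULL

  # feature layout: one origin per tandem unit; telomere over the chrY repeat
  # end; centromere, LTRs, retrotransposon, introns, genes on unique contigs
  feats <- list()
  add_feat <- function(kind, contig, start, end, name) {
    len <- contig_table$length[contig_table$name == contig]
    if (end > len) return(invisible())   # skip on very small toy contigs
    feats[[length(feats) + 1L]] <<- data.frame(kind = kind, contig = contig,
                                               start = start, end = end,
                                               name = name)
  }
  for (i in seq_len(tandem_units)) {
    u0 <- tandem_start + (i - 1L) * tandem_unit_length
    add_feat("origin", tandem_contig, u0 + 100L, u0 + 250L,
             sprintf("ARS_rDNA_%02d", i))
    add_feat("rRNA", tandem_contig, u0 + 300L, u0 + 900L,
             sprintf("RDN_%02d", i))
  }
  # replication origins on a regular grid over the unique contigs, so that
  # origin overlap with circles is a baseline occurrence, not a planted signal
  for (nm in names(unique_sizes)) {
    ars_at <- seq(5000L, unique_sizes[[nm]] - 5000L, by = 10000L)
    for (k in seq_along(ars_at))
      add_feat("origin", nm, ars_at[k], ars_at[k] + 150L,
               sprintf("ARS_%s_%02d", nm, k))
  }
  add_feat("telomere", disp_contig, lead - 2000L,
           contig_table$length[contig_table$name == disp_contig], "TEL_Y")
  u1 <- names(unique_sizes)[1]
  l1 <- unique_sizes[[1]]
  at <- function(len, frac) as.integer(len * frac)
  add_feat("centromere", u1, at(l1, 0.5), at(l1, 0.5) + 120L, "CEN_U1")
  add_feat("LTR", u1, at(l1, 0.17), at(l1, 0.17) + 330L, "LTR_delta1")
  add_feat("intron", u1, at(l1, 0.75) + 500L, at(l1, 0.75) + 800L, "INT_1")
  add_feat("gene", u1, at(l1, 0.75), at(l1, 0.75) + 2000L, "GENE_A")
  if (length(unique_sizes) > 1L) {
    u2 <- names(unique_sizes)[2]
    l2 <- unique_sizes[[2]]
    add_feat("LTR", u2, at(l2, 0.45), at(l2, 0.45) + 330L, "LTR_delta2")
    add_feat("retrotransposon", u2, at(l2, 0.7), at(l2, 0.7) + 5900L, "Ty1_1")
    add_feat("gene", u2, at(l2, 0.1), at(l2, 0.1) + 2000L, "GENE_B")
    add_feat("tRNA", u2, at(l2, 0.3), at(l2, 0.3) + 90L, "tA_1")
  }
  features <- do.call(rbind, feats)
  validate_features(features, contig_table)

  genome <- structure(list(
    contigs = Biostrings::DNAStringSet(unlist(seqs)),
    contig_table = contig_table,
    tandem = list(contig = tandem_contig, start = tandem_start,
                  end = tandem_end, unit_length = tandem_unit_length,
                  n_units = tandem_units),
    dispersed = dispersed,
    divergence = divergence,
    features = features
  ), class = "ecc_genome")
  genome
}

FEATURE_KINDS <- c("origin", "centromere", "LTR", "telomere",
                   "retrotransposon", "intron", "gene", "rRNA", "tRNA")

validate_features <- function(features, contig_table) {
  bad <- setdiff(unique(features$kind), FEATURE_KINDS)
  if (length(bad)) stop("unknown feature kind: ", paste(bad, collapse = ", "))
  if (any(features$start >= features$end))
    stop("feature with start >= end")
  len <- stats::setNames(contig_table$length, contig_table$name)
  if (any(features$end > len[features$contig]))
    stop("feature interval outside its contig")
  invisible(features)
}

# run code under a temporary RNG state restored on exit; returns the restorer
local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Write genome FASTA and feature annotations
#'
#' Writes the genome as FASTA, and the feature table as 6-column BED and GFF3.
#' BED is 0-based half-open; GFF3 is 1-based closed.
#'
#' @param genome an `ecc_genome`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome$contigs, fa)
  f <- genome$features
  bed <- file.path(dir, "features.bed")
  bed_df <- data.frame(f$contig, f$start, f$end, f$name, 0L, "+")
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gff <- file.path(dir, "features.gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\tecclineage\t%s\t%d\t%d\t.\t+\t.\tID=%s;kind=%s",
                     f$contig, f$kind, f$start + 1L, f$end, f$name, f$kind))
  writeLines(lines, gff)
  invisible(c(fasta = fa, bed = bed, gff3 = gff))
}

#' Read a feature BED written by [write_genome_files()]
#'
#' @param path BED file (6 columns, name in column 4).
#' @param kinds optional vector assigning a kind per row; defaults to "gene".
#' @return data.frame with kind, contig, start, end, name.
#' @export
read_features_bed <- function(path, kinds = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (any(df[[2]] >= df[[3]]))
    stop("BED interval with start >= end at line ",
         which(df[[2]] >= df[[3]])[1])
  out <- data.frame(kind = if (is.null(kinds)) "gene" else kinds,
                    contig = df[[1]], start = df[[2]], end = df[[3]],
                    name = df[[4]])
  out
}

#' Extract the reference sequence of an interval
#'
#' @param genome an `ecc_genome`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @return character scalar sequence.
#' @export
genome_sequence <- function(genome, contig, start, end) {
  if (!contig %in% names(genome$contigs)) stop("unknown contig: ", contig)
  as.character(Biostrings::subseq(genome$contigs[[contig]], start + 1L, end))
}
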