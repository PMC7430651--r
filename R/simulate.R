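#' Simulate Circle-Seq alignment records for one sample
#'
#' Emits the read-level evidence structure that rolling-circle-amplified,
#' short-read sequenced circular DNA leaves in a coordinate-sorted alignment
#' file, without base-level sequence realism:
#'
#' * unique-mode circles produce junction reads (soft-clipped at one circle
#'   boundary, the clipped segment mapping to the other boundary),
#'   outward-oriented discordant pairs inside the circle, and concordant
#'   internal reads tiled evenly across the covered span;
#' * repeat-mode circles produce fully aligned multi-mapping reads (low
#'   mapping quality) carrying XA-style alternative hits at homologous repeat
#'   copies — tandem-array circles have no soft-clipped reads because the
#'   junction sequence is indistinguishable from the array itself;
#' * spike-in plasmid contigs and low-level linear background receive plain
#'   high-quality reads.
#'
#' Sequencing error appears only as edit-distance (NM) noise. Every emitted
#' record is primary, so the number of records equals the sum of requested
#' depths plus background plus spike-ins.
#'
#' @param genome an `ecc_genome`.
#' @param cohort a cohort from [plan_circle_cohort()].
#' @param sample sample id present in the cohort's sheet.
#' @param read_length read length in bases (must be shorter than every circle).
#' @param error_rate per-base error rate injected as NM noise.
#' @param rca_factor multiplier applied to circle read depths (depth inflation
#'   by rolling-circle amplification; the default cohort library model already
#'   folds amplification into its abundances, so the default is 1).
#' @param seed integer seed.
#' @return data.frame of alignment records, coordinate-sorted, with columns
#'   qname, contig, start (0-based), aln_len, strand, mapq, clip_left,
#'   clip_right, sa_contig, sa_pos, sa_strand, mate_contig, mate_pos,
#'   mate_strand, nm, xa, secondary.
#' @export
simulate_alignments <- function(genome, cohort, sample, read_length = 100L,
                                error_rate = 0.001, rca_factor = 1,
                                seed = 1L) {
  stopifnot(inherits(genome, "ecc_genome"))
  if (!sample %in% cohort$sheet$sample)
    stop("sample not in sheet: ", sample)
  restore <- local_seed(seed + match(sample, cohort$sheet$sample) * 104729L)
  on.exit(restore(), add = TRUE)
  R <- as.integer(read_length)

  circles <- cohort$circles
  dep <- cohort$depths[cohort$depths$sample == sample, ]
  dep <- dep[match(circles$circle_id, dep$circle_id), ]
  if (any(dep$depth > 0L & (circles$end - circles$start) <= R))
    stop("read length must be shorter than every planted circle")

  recs <- list()
  emit <- function(df) recs[[length(recs) + 1L]] <<- df

  blank <- function(n) data.frame(
    qname = character(n), contig = character(n), start = integer(n),
    aln_len = rep(R, n), strand = rep("+", n), mapq = rep(60L, n),
    clip_left = integer(n), clip_right = integer(n),
    sa_contig = rep(NA_character_, n), sa_pos = rep(NA_integer_, n),
    sa_strand = rep(NA_character_, n), mate_contig = rep(NA_character_, n),
    mate_pos = rep(NA_integer_, n), mate_strand = rep(NA_character_, n),
    nm = integer(n), xa = rep(NA_character_, n), secondary = logical(n),
    stringsAsFactors = FALSE)

  td <- genome$tandem
  for (i in seq_len(nrow(circles))) {
    d <- dep$depth[i]
    if (rca_factor != 1 && d > 0L) d <- max(1L, as.integer(round(d * rca_factor)))
    if (d == 0L) next
    cid <- circles$circle_id[i]
    ctg <- circles$contig[i]
    cs <- circles$start[i]; ce <- circles$end[i]
    len <- ce - cs

    if (circles$mode[i] == "unique") {
      n_j <- min(dep$n_junction[i], d)
      n_p <- min(dep$n_discordant_pairs[i], (d - n_j) %/% 2L)
      n_int <- d - n_j - 2L * n_p
      qbase <- paste0(sample, "_", cid)

      if (n_j > 0L) {
        j <- seq_len(n_j)
        cl <- 20L + (j * 13L) %% max(1L, R - 40L)
        formA <- j %% 2L == 1L
        b <- blank(n_j)
        b$qname <- sprintf("%s_j%04d", qbase, j)
        b$contig <- ctg
        b$aln_len <- R - cl
        # form A: aligned tail ends at circle end, clip maps to circle start
        b$start[formA] <- ce - (R - cl[formA])
        b$clip_right[formA] <- cl[formA]
        b$sa_pos[formA] <- cs
        # form B: aligned head starts at circle start, clip maps near the end
        b$start[!formA] <- cs
        b$clip_left[!formA] <- cl[!formA]
        b$sa_pos[!formA] <- ce - cl[!formA]
        b$sa_contig <- ctg
        b$sa_strand <- "+"
        b$mate_contig <- ctg
        b$mate_pos <- cs + len %/% 2L
        b$mate_strand <- "-"
        emit(b)
      }

      if (n_p > 0L) {
        j <- seq_len(n_p)
        inner <- max(len - 2L * R - 20L, 10L)
        p1 <- cs + 10L + (j * 17L) %% max(1L, inner %/% 2L)
        p2 <- ce - R - 10L - (j * 11L) %% max(1L, inner %/% 2L)
        p2 <- pmax(p2, p1 + 1L)
        b1 <- blank(n_p); b2 <- blank(n_p)
        qn <- sprintf("%s_d%04d", qbase, j)
        b1$qname <- qn; b2$qname <- qn
        b1$contig <- ctg; b2$contig <- ctg
        b1$start <- p1; b1$strand <- "-"
        b1$mate_contig <- ctg; b1$mate_pos <- p2; b1$mate_strand <- "+"
        b2$start <- p2; b2$strand <- "+"
        b2$mate_contig <- ctg; b2$mate_pos <- p1; b2$mate_strand <- "-"
        emit(b1); emit(b2)
      }

      if (n_int > 0L) {
        span <- max(R + 1L, as.integer(round(circles$span_frac[i] * len)))
        hi <- cs + span - R
        pos <- if (n_int == 1L) cs else
          cs + as.integer(round(seq(0, hi - cs, length.out = n_int)))
        b <- blank(n_int)
        b$qname <- sprintf("%s_i%04d", qbase, seq_len(n_int))
        b$contig <- ctg
        b$start <- pos
        b$mate_contig <- ctg
        b$mate_pos <- pmin(pos + 200L, hi)
        b$mate_strand <- "-"
        emit(b)
      }
    } else {
      # repeat-mode: fully aligned multireads with alternative hits
      j <- seq_len(d)
      pos <- cs + as.integer(round(seq(0, len - R, length.out = max(d, 2L))))[j]
      b <- blank(d)
      b$qname <- sprintf("%s_%s_m%05d", sample, cid, j)
      b$contig <- ctg
      b$mapq <- 3L
      alt_nm_extra <- max(1L, as.integer(ceiling(genome$divergence * R)))
      b$start <- pos
      if (ctg == td$contig && cs >= td$start && ce <= td$end) {
        # tandem array: equally good hits at the homologous position of every
        # other unit copy spanned by the circle
        ul <- td$unit_length
        unit_of <- (pos - td$start) %/% ul
        units_in <- ((cs - td$start) %/% ul):(((ce - td$start) %/% ul) - 1L)
        off <- pmin((pos - td$start) %% ul, ul - R)
        b$xa <- vapply(seq_len(d), function(r) {
          alts <- setdiff(units_in, unit_of[r])
          paste(sprintf("%s,%d,+,%d", ctg, td$start + alts * ul + off[r],
                        alt_nm_extra), collapse = ";")
        }, character(1))
      } else {
        # dispersed copies: hits at the homologous offset of every other copy
        dsp <- genome$dispersed[genome$dispersed$contig == ctg &
                                  genome$dispersed$start >= cs &
                                  genome$dispersed$end <= ce, ]
        if (nrow(dsp) < 2L)
          stop("repeat circle must span >= 2 repeat copies: ", cid)
        cw <- dsp$end[1] - dsp$start[1]
        k <- findInterval(pos, dsp$start)
        k[k < 1L] <- 1L
        off <- pmin(pmax(pos - dsp$start[k], 0L), cw - R)
        b$xa <- vapply(seq_len(d), function(r) {
          alts <- setdiff(seq_len(nrow(dsp)), k[r])
          paste(sprintf("%s,%d,+,%d", ctg, dsp$start[alts] + off[r],
                        alt_nm_extra), collapse = ";")
        }, character(1))
      }
      emit(b)
    }
  }

  # spike-in plasmid reads: tiled, high quality
  for (pl in names(cohort$spikein_depths[[sample]])) {
    n <- cohort$spikein_depths[[sample]][[pl]]
    if (n == 0L) next
    plen <- genome$contig_table$length[genome$contig_table$name == pl]
    b <- blank(n)
    b$qname <- sprintf("%s_%s_s%05d", sample, pl, seq_len(n))
    b$contig <- pl
    b$start <- as.integer(round(seq(0, plen - R, length.out = max(n, 2L))))[seq_len(n)]
    emit(b)
  }

  # linear background on unique contigs
  n_bg <- cohort$background_depths[[sample]]
  if (n_bg > 0L) {
    uni <- genome$contig_table[genome$contig_table$region_class == "unique", ]
    pick <- sample.int(nrow(uni), n_bg, replace = TRUE)
    b <- blank(n_bg)
    b$qname <- sprintf("%s_bg%05d", sample, seq_len(n_bg))
    b$contig <- uni$name[pick]
    b$start <- as.integer(floor(stats::runif(n_bg) * (uni$length[pick] - R)))
    emit(b)
  }

  if (!length(recs)) return(empty_alignments())
  out <- do.call(rbind, recs)
  if (error_rate > 0) {
    noise <- stats::rbinom(nrow(out), R, error_rate)
    out$nm <- out$nm + ifelse(out$mapq >= 20L, noise, 0L)
  }
  out <- out[order(match(out$contig, names(genome$contigs)), out$start,
                   out$qname), ]
  rownames(out) <- NULL
  out
}

#' Simulate every sample of a cohort
#'
#' @inheritParams simulate_alignments
#' @return named list of alignment data.frames, one per sample in the sheet.
#' @export
simulate_cohort <- function(genome, cohort, read_length = 100L,
                            error_rate = 0.001, seed = 1L) {
  out <- lapply(cohort$sheet$sample, function(s)
    simulate_alignments(genome, cohort, s, read_length = read_length,
                        error_rate = error_rate, seed = seed))
  stats::setNames(out, cohort$sheet$sample)
}
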