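#' Sample sheet for a population design
#'
#' One Circle-Seq library per (population, subpopulation). Populations are
#' biological replicates of the mother-enrichment aging experiment; each is
#' split into `young` (sampled before aging), `progeny` (daughters of the
#' aging mothers) and `aged` (the mothers after ~15 divisions).
#'
#' @param populations character vector of population ids.
#' @param subpopulations subset of `c("young", "progeny", "aged")`.
#' @return data.frame with columns sample, population, subpopulation.
#' @export
make_sample_sheet <- function(populations = c("P1", "P2"),
                              subpopulations = c("young", "progeny", "aged")) {
  stopifnot(all(subpopulations %in% SUBPOPS))
  df <- expand.grid(population = populations, subpopulation = subpopulations,
                    stringsAsFactors = FALSE)
  df <- df[order(df$population, match(df$subpopulation, SUBPOPS)), ]
  df <- data.frame(sample = paste(df$population, df$subpopulation, sep = "_"),
                   df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

SUBPOPS <- c("young", "progeny", "aged")
CLASSES <- c("I", "II", "III", "IV", "V")

# presence pattern of each inheritance class over (young, progeny, aged)
class_pattern <- function(class) {
  switch(class,
         I   = c(young = TRUE,  progeny = TRUE,  aged = TRUE),
         II  = c(young = TRUE,  progeny = FALSE, aged = TRUE),
         III = c(young = TRUE,  progeny = TRUE,  aged = FALSE),
         IV  = c(young = TRUE,  progeny = FALSE, aged = FALSE),
         V   = c(young = FALSE, progeny = FALSE, aged = TRUE),
         stop("unknown class: ", class))
}

#' Default planted-circle design
#'
#' The study conditions the simulator emulates: one population pair, a young
#' circle repertoire dominated by class IV (circles lost on aging; 60 of 64
#' young circles = 93.75%), an rDNA-like tandem-array circle (class I) whose
#' abundance is inflated 400-fold in aged samples, a Y'-like dispersed-repeat
#' circle (class II) inflated 600-fold, two de novo (class V) circles, one
#' circle planted with conflicting per-population patterns (I in P1, IV in P2;
#' resolves to I), one same-order conflict (II in P1, III in P2; ambiguous),
#' and three detection controls: a unique circle with only 4 junction reads
#' (below the >4 support cut), a unique circle covered over only half its
#' length (below the >90% coverage cut), and a tandem-array circle with 19
#' multi-mapping reads (below the repeat-mode support cut of 20). Two class IV
#' circles carry 3 sub-threshold junction reads in aged samples so the
#' unfiltered rescue re-intersection has material (58/60 with zero evidence).
#'
#' @return a list understood by [plan_circle_cohort()].
#' @export
default_cohort_design <- function() {
  list(
    class_counts = c(I = 0L, II = 0L, III = 1L, IV = 60L, V = 2L),
    n_conflict_resolved = 1L,
    n_conflict_ambiguous = 1L,
    rdna = list(class = "I", units = 5L:9L, abundance = 180, aged_factor = 400),
    yprime = list(class = "II", abundance = 1.5, aged_factor = 600),
    controls = TRUE,
    aged_leak = list(n_circles = 2L, reads = 3L),
    base_abundance = 1,
    plasmid_abundance = 25,
    background_abundance = 10,
    library_size = 30000L,
    depth_floor = 35L,
    n_cells_recovered = 10000L
  )
}

#' Plan a cohort of planted circles with designed inheritance
#'
#' Places circles on the toy genome and assigns per-sample read depths that
#' realize each circle's truth class. Depths follow a library model: every
#' sample is sequenced to `library_size` primary reads, split across the
#' molecules present in that sample proportionally to their relative
#' abundance (circles present per the class pattern, spike-in plasmids at
#' constant abundance, and low-level linear background). Aged inflation of the
#' rDNA-like and Y'-like circles therefore compresses every other category's
#' read share, as in real rolling-circle-amplified libraries.
#'
#' @param genome an `ecc_genome` from [build_toy_genome()].
#' @param design list as returned by [default_cohort_design()].
#' @param sheet sample sheet from [make_sample_sheet()].
#' @param seed integer seed (placement and size jitter).
#' @return list with `circles` (one row per planted circle: circle_id, contig,
#'   start, end, mode, class, flags), `depths` (long data.frame: circle_id,
#'   sample, depth, n_junction, n_discordant_pairs), `spikein_depths` and
#'   `background_depths` (per-sample), and `sheet`.
#' @export
plan_circle_cohort <- function(genome, design = default_cohort_design(),
                               sheet = make_sample_sheet(), seed = 1L) {
  stopifnot(inherits(genome, "ecc_genome"))
  restore <- local_seed(seed + 7919L)
  on.exit(restore(), add = TRUE)
  cc <- design$class_counts
  if (any(cc < 0L)) stop("class counts must be >= 0")
  if (!all(names(cc) %in% CLASSES)) stop("unknown class in design")

  rows <- list()
  uid <- 0L
  new_circle <- function(contig, start, end, mode, class, junction_frac = NA,
                         span_frac = 1, abundance = design$base_abundance,
                         aged_factor = 1, fixed_depth = NA, leak = 0L,
                         pattern_by_pop = NULL, rdna = FALSE) {
    uid <<- uid + 1L
    rows[[uid]] <<- list(circle_id = sprintf("circ%03d", uid), contig = contig,
                         start = start, end = end, mode = mode, class = class,
                         junction_frac = junction_frac, span_frac = span_frac,
                         abundance = abundance, aged_factor = aged_factor,
                         fixed_depth = fixed_depth, leak = leak,
                         pattern_by_pop = list(pattern_by_pop), rdna = rdna)
  }

  # -- placement on unique contigs: non-overlapping slots on a 2 kb grid
  uni <- genome$contig_table[genome$contig_table$region_class == "unique", ]
  slots <- do.call(rbind, lapply(seq_len(nrow(uni)), function(i) {
    starts <- seq(2000L, uni$length[i] - 4000L, by = 2000L)
    data.frame(contig = uni$name[i], start = starts)
  }))
  slots <- slots[sample.int(nrow(slots)), ]
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    if (slot_i > nrow(slots)) stop("design needs more unique-contig slots")
    slots[slot_i, ]
  }
  place_unique <- function(class, ...) {
    s <- next_slot()
    len <- sample(600:1400, 1L)
    new_circle(s$contig, s$start, s$start + len, "unique", class, ...)
  }

  for (cl in CLASSES) {
    n <- if (cl %in% names(cc)) cc[[cl]] else 0L
    for (k in seq_len(n)) {
      if (cl == "V" && k %% 2L == 0L) {
        # de novo circles are "aged and/or progeny": alternate the two forms
        pops <- unique(sheet$population)
        pat <- stats::setNames(rep(list(c(young = FALSE, progeny = TRUE,
                                          aged = FALSE)), length(pops)), pops)
        place_unique("V", pattern_by_pop = pat)
      } else {
        place_unique(cl)
      }
    }
  }

  # conflicting patterns (per-population class override)
  for (k in seq_len(design$n_conflict_resolved %||% 0L)) {
    pops <- unique(sheet$population)
    pat <- stats::setNames(rep(list(class_pattern("IV")), length(pops)), pops)
    pat[[1L]] <- class_pattern("I")
    place_unique("I", pattern_by_pop = pat)   # truth resolves to I
  }
  for (k in seq_len(design$n_conflict_ambiguous %||% 0L)) {
    pops <- unique(sheet$population)
    pat <- stats::setNames(rep(list(class_pattern("III")), length(pops)), pops)
    pat[[1L]] <- class_pattern("II")
    place_unique("ambiguous", pattern_by_pop = pat)
  }

  # rDNA-like circle spanning several tandem units
  td <- genome$tandem
  if (!is.null(design$rdna)) {
    u <- design$rdna$units
    new_circle(td$contig, td$start + (min(u) - 1L) * td$unit_length,
               td$start + max(u) * td$unit_length, "repeat", design$rdna$class,
               abundance = design$rdna$abundance,
               aged_factor = design$rdna$aged_factor, rdna = TRUE)
  }
  # Y'-like circle: the whole cluster of dispersed copies (multi-copy circles
  # are resolvable; a single-copy repeat circle is not, see methods vignette)
  if (!is.null(design$yprime)) {
    dsp <- genome$dispersed
    new_circle(dsp$contig[1], dsp$start[1], dsp$end[nrow(dsp)], "repeat",
               design$yprime$class,
               abundance = design$yprime$abundance,
               aged_factor = design$yprime$aged_factor)
  }

  # detection controls: young-only presence, fixed read counts
  if (isTRUE(design$controls)) {
    place_unique("IV", junction_frac = 1, fixed_depth = 4L, abundance = 0)
    place_unique("IV", span_frac = 0.5, fixed_depth = 60L, abundance = 0)
    u0 <- td$start + 10L * td$unit_length          # units 11-15
    new_circle(td$contig, u0, u0 + 5L * td$unit_length, "repeat", "IV",
               fixed_depth = 19L, abundance = 0)
  }

  if (!length(rows)) {
    circles <- data.frame(circle_id = character(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          mode = character(0), class = character(0),
                          junction_frac = numeric(0), span_frac = numeric(0),
                          abundance = numeric(0), aged_factor = numeric(0),
                          fixed_depth = integer(0), leak = integer(0),
                          rdna = logical(0), stringsAsFactors = FALSE)
    circles$pattern_by_pop <- list()
  } else {
    circles <- do.call(rbind, lapply(rows, function(r)
      data.frame(r[setdiff(names(r), "pattern_by_pop")],
                 stringsAsFactors = FALSE)))
    circles$pattern_by_pop <- lapply(rows, function(r) r$pattern_by_pop[[1]])
  }

  # leak reads: first `n` plain class IV circles get sub-threshold aged reads
  if (!is.null(design$aged_leak) && design$aged_leak$n_circles > 0L) {
    plain_iv <- which(circles$class == "IV" & circles$mode == "unique" &
                        is.na(circles$fixed_depth))
    take <- utils::head(plain_iv, design$aged_leak$n_circles)
    circles$leak[take] <- design$aged_leak$reads
  }

  # -- per-sample depth assignment via the library model
  present <- function(i, pop, sub) {
    pat <- circles$pattern_by_pop[[i]]
    if (!is.null(pat)) return(isTRUE(pat[[pop]][[sub]]))
    isTRUE(class_pattern(circles$class[i])[[sub]])
  }
  depth_rows <- list(); spike <- list(); bg <- integer(0)
  plasmid_names <- genome$contig_table$name[
    genome$contig_table$region_class == "plasmid"]
  for (s in seq_len(nrow(sheet))) {
    pop <- sheet$population[s]; sub <- sheet$subpopulation[s]
    pres <- vapply(seq_len(nrow(circles)), present, logical(1),
                   pop = pop, sub = sub)
    ab <- ifelse(pres, circles$abundance, 0)
    ab <- ab * ifelse(pres & sub == "aged", circles$aged_factor, 1)
    pl_ab <- rep(design$plasmid_abundance, length(plasmid_names))
    tot <- sum(ab) + sum(pl_ab) + design$background_abundance
    L <- design$library_size
    depth <- as.integer(round(L * ab / tot))
    # detectability floor: real libraries run tens of millions of reads, so a
    # truly present circle stays above the detection cut even when the aged
    # library is dominated by rDNA circles; the toy library keeps that depth
    # structure without the full read count. Plasmids and background stay
    # strictly proportional, so spike-normalized ratios track abundance.
    floor_on <- pres & circles$abundance > 0
    depth[floor_on] <- pmax(depth[floor_on], design$depth_floor %||% 0L)
    fixed <- !is.na(circles$fixed_depth) & pres
    depth[fixed] <- circles$fixed_depth[fixed]
    leak_on <- sub == "aged" & circles$leak > 0L & depth == 0L
    depth[leak_on] <- circles$leak[leak_on]
    jf <- ifelse(is.na(circles$junction_frac), 0.2, circles$junction_frac)
    jf[leak_on] <- 1                                  # leaks are junction reads
    n_j <- ifelse(circles$mode == "unique" & depth > 0L,
                  pmax(1L, as.integer(round(jf * depth))), 0L)
    n_j <- pmin(n_j, depth)
    n_d <- ifelse(circles$mode == "unique", depth %/% 20L, 0L)
    n_d <- pmin(as.integer(n_d), pmax(0L, (depth - n_j) %/% 2L))
    depth_rows[[s]] <- data.frame(circle_id = circles$circle_id,
                                  sample = rep(sheet$sample[s],
                                               nrow(circles)),
                                  depth = depth,
                                  n_junction = n_j,
                                  n_discordant_pairs = n_d,
                                  stringsAsFactors = FALSE)
    spike[[s]] <- stats::setNames(
      as.integer(round(L * pl_ab / tot)), plasmid_names)
    bg[s] <- as.integer(round(L * design$background_abundance / tot))
  }
  depths <- do.call(rbind, depth_rows)
  rownames(depths) <- NULL

  validate_cohort(circles, depths, sheet)
  list(circles = circles, depths = depths,
       spikein_depths = stats::setNames(spike, sheet$sample),
       background_depths = stats::setNames(bg, sheet$sample),
       sheet = sheet, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# class/presence consistency: a circle's depths must realize its truth class.
# Class IV tolerates sub-detection-threshold aged reads (the rescue check
# exists to count exactly those); everything else must be structurally absent.
validate_cohort <- function(circles, depths, sheet, max_leak = 4L) {
  d <- merge(depths, sheet, by = "sample")
  for (i in seq_len(nrow(circles))) {
    if (!is.null(circles$pattern_by_pop[[i]])) next
    cl <- circles$class[i]
    if (!cl %in% CLASSES) next
    di <- d[d$circle_id == circles$circle_id[i], ]
    pat <- class_pattern(cl)
    for (sub in SUBPOPS) {
      dep <- di$depth[di$subpopulation == sub]
      if (pat[[sub]]) {
        if (!all(dep > 0L))
          stop("circle ", circles$circle_id[i], " (class ", cl,
               ") lacks depth in ", sub)
      } else {
        lim <- if (cl == "IV" && sub != "young") max_leak else 0L
        if (any(dep > lim))
          stop("circle ", circles$circle_id[i], " (class ", cl,
               ") has depth in ", sub, " inconsistent with its class")
      }
    }
  }
  invisible(TRUE)
}

#' Truth table of planted circles
#'
#' One row per planted circle per sample carrying its truth class and the
#' requested read decomposition; the companion of every simulated SAM.
#'
#' @param cohort result of [plan_circle_cohort()].
#' @return data.frame.
#' @export
cohort_truth_table <- function(cohort) {
  merge(cohort$circles[, c("circle_id", "contig", "start", "end", "mode",
                           "class", "span_frac")],
        cohort$depths, by = "circle_id", sort = FALSE)
}
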