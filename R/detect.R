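#' Extract junction evidence from coordinate-sorted alignments
#'
#' Collects the read-level signatures of a circular junction:
#'
#' * `soft_clip` / `split`: a read soft-clipped by at least `min_clip` bases.
#'   When the clipped segment's mapped position is known (SA tag) the implied
#'   interval spans from the leftmost to the rightmost coordinate among the
#'   aligned segment and the clipped segment — the two circle boundaries.
#'   Without a mapped clip position the read span extended by the clip is used.
#' * `discordant`: an outward-oriented pair (leftmost mate on the minus
#'   strand, its partner downstream on the plus strand), the orientation a
#'   read pair acquires when its fragment crosses a circular junction. The
#'   implied interval spans the pair.
#'
#' @param alignments alignment data.frame, coordinate-sorted; an unsorted
#'   input is an error naming the first out-of-order record.
#' @param min_clip minimum soft-clip length to count as junction evidence.
#' @return data.frame: qname, kind, contig, start, end, mapq.
#' @export
extract_junction_evidence <- function(alignments, min_clip = 10L) {
  a <- alignments
  if (nrow(a) > 1L) {
    same <- a$contig[-1L] == a$contig[-nrow(a)]
    bad <- which(same & diff(a$start) < 0L)
    if (length(bad))
      stop("alignments not coordinate-sorted at record ", bad[1] + 1L,
           " (", a$qname[bad[1] + 1L], ")")
  }
  a <- a[!a$secondary, , drop = FALSE]
  ev <- list()

  clip <- pmax(a$clip_left, a$clip_right) >= min_clip
  with_sa <- clip & !is.na(a$sa_pos) & !is.na(a$sa_contig) &
    a$sa_contig == a$contig
  if (any(with_sa)) {
    s <- a[with_sa, ]
    cliplen <- pmax(s$clip_left, s$clip_right)
    ev[[length(ev) + 1L]] <- data.frame(
      qname = s$qname, kind = "split", contig = s$contig,
      start = pmin(s$start, s$sa_pos),
      end = pmax(s$start + s$aln_len, s$sa_pos + cliplen),
      mapq = s$mapq, stringsAsFactors = FALSE)
  }
  no_sa <- clip & !with_sa
  if (any(no_sa)) {
    s <- a[no_sa, ]
    ev[[length(ev) + 1L]] <- data.frame(
      qname = s$qname, kind = "soft_clip", contig = s$contig,
      start = s$start - s$clip_left,
      end = s$start + s$aln_len + s$clip_right,
      mapq = s$mapq, stringsAsFactors = FALSE)
  }
  disc <- !clip & !is.na(a$mate_contig) & a$mate_contig == a$contig &
    a$strand == "-" & !is.na(a$mate_strand) & a$mate_strand == "+" &
    a$mate_pos > a$start
  if (any(disc)) {
    s <- a[disc, ]
    ev[[length(ev) + 1L]] <- data.frame(
      qname = s$qname, kind = "discordant", contig = s$contig,
      start = s$start, end = s$mate_pos + s$aln_len,
      mapq = s$mapq, stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(qname = character(0), kind = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), mapq = integer(0)))
  out <- do.call(rbind, ev)
  out <- out[out$start < out$end, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$end, out$qname), ]
  rownames(out) <- NULL
  out
}

# greedy single-pass clustering of intervals: items (sorted by contig, start)
# join the first open cluster whose consensus interval they reciprocally
# overlap by >= frac; consensus = min start / max end of members.
# Returns per-item cluster id.
cluster_intervals <- function(contig, start, end, frac) {
  n <- length(start)
  id <- integer(n)
  if (!n) return(id)
  ord <- order(contig, start, end)
  cs <- integer(0); ce <- integer(0); cc <- character(0)
  for (k in ord) {
    s <- start[k]; e <- end[k]; ctg <- contig[k]
    assigned <- 0L
    if (length(cs)) {
      live <- which(cc == ctg & cs < e & ce > s)
      for (j in live) {
        ov <- min(e, ce[j]) - max(s, cs[j])
        if (ov / (e - s) >= frac && ov / (ce[j] - cs[j]) >= frac) {
          assigned <- j
          break
        }
      }
    }
    if (assigned == 0L) {
      cs <- c(cs, s); ce <- c(ce, e); cc <- c(cc, ctg)
      assigned <- length(cs)
    } else {
      cs[assigned] <- min(cs[assigned], s)
      ce[assigned] <- max(ce[assigned], e)
    }
    id[k] <- assigned
  }
  id
}

#' Iteratively merge reciprocally overlapping circle calls
#'
#' Two calls merge when each overlaps the other over at least `min_frac` of
#' its own length; the merged call is the union interval with summed support.
#' Merging iterates to a fixed point and the result is sorted by
#' (contig, start), so it does not depend on the input order.
#'
#' @param calls data.frame with contig, start, end, support (other columns
#'   are carried from the first member of each merge).
#' @param min_frac reciprocal-overlap fraction in (0, 1]; 0.5 for unique-mode
#'   calls, 0.8 for repeat-mode calls.
#' @return merged call data.frame.
#' @export
merge_reciprocal <- function(calls, min_frac) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac > 1)
    stop("min_frac must be in (0, 1]")
  x <- calls[order(calls$contig, calls$start, calls$end), , drop = FALSE]
  repeat {
    n <- nrow(x)
    if (n < 2L) break
    merged_any <- FALSE
    for (i in seq_len(n - 1L)) {
      e_i <- x$end[i]
      js <- which(x$contig == x$contig[i] & x$start < e_i & x$end > x$start[i])
      js <- js[js != i]
      for (j in js) {
        ov <- min(e_i, x$end[j]) - max(x$start[i], x$start[j])
        if (ov / (e_i - x$start[i]) >= min_frac &&
            ov / (x$end[j] - x$start[j]) >= min_frac) {
          x$start[i] <- min(x$start[i], x$start[j])
          x$end[i] <- max(e_i, x$end[j])
          x$support[i] <- x$support[i] + x$support[j]
          x <- x[-j, , drop = FALSE]
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
    x <- x[order(x$contig, x$start, x$end), , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Fraction of an interval covered by eligible reads
#'
#' The fraction of positions in `[start, end)` covered by at least one
#' eligible aligned read (aligned segments only; soft-clipped bases do not
#' cover). In unique mode, eligible means mapping quality >= `min_mapq`;
#' in repeat mode, pass the pre-selected reads and `min_mapq = 0`.
#'
#' @param alignments alignment data.frame.
#' @param contig,start,end the interval (0-based half-open; empty is an error).
#' @param min_mapq mapping-quality floor for eligibility.
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(alignments, contig, start, end, min_mapq = 20L) {
  if (end <= start) stop("empty interval")
  a <- alignments[alignments$contig == contig & alignments$mapq >= min_mapq &
                    !alignments$secondary, , drop = FALSE]
  if (!nrow(a)) return(0)
  ir <- IRanges::IRanges(start = a$start + 1L, width = a$aln_len)
  ir <- IRanges::restrict(ir, start = start + 1L, end = end)
  ir <- ir[IRanges::width(ir) > 0L]
  if (!length(ir)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  covered / (end - start)
}

#' Call circles from unique genomic regions
#'
#' Clusters co-locating junction evidence into candidate intervals (consensus
#' = leftmost start / rightmost end of members), merges candidates that
#' reciprocally overlap by `merge_frac`, then keeps calls with more than
#' `min_support - 1` distinct supporting junction reads and sequencing
#' coverage strictly above `min_coverage`.
#'
#' @param evidence junction evidence from [extract_junction_evidence()].
#' @param alignments the sample's alignments (for coverage).
#' @param sample sample id stamped on the calls.
#' @param min_support minimum distinct supporting reads (kept when
#'   `support >= min_support`; the default 5 encodes "more than 4").
#' @param min_coverage coverage fraction, kept when strictly greater.
#' @param merge_frac reciprocal-overlap fraction for candidate merging.
#' @param min_mapq mapping-quality floor for coverage eligibility.
#' @return call data.frame: contig, start, end, name, support, mode,
#'   coverage_fraction, sample.
#' @export
call_unique_circles <- function(evidence, alignments, sample = NA_character_,
                                min_support = 5L, min_coverage = 0.9,
                                merge_frac = 0.5, min_mapq = 20L) {
  if (!nrow(evidence)) return(empty_calls())
  cl <- cluster_intervals(evidence$contig, evidence$start, evidence$end,
                          merge_frac)
  agg <- split(seq_len(nrow(evidence)), cl)
  calls <- do.call(rbind, lapply(agg, function(ix) data.frame(
    contig = evidence$contig[ix[1]],
    start = min(evidence$start[ix]),
    end = max(evidence$end[ix]),
    support = length(unique(evidence$qname[ix])),
    stringsAsFactors = FALSE)))
  calls <- merge_reciprocal(calls, merge_frac)
  calls$coverage_fraction <- vapply(seq_len(nrow(calls)), function(i)
    coverage_fraction(alignments, calls$contig[i], calls$start[i],
                      calls$end[i], min_mapq = min_mapq), numeric(1))
  calls <- calls[calls$support >= min_support &
                   calls$coverage_fraction > min_coverage, , drop = FALSE]
  finish_calls(calls, "unique", sample)
}

#' Call circles from repetitive regions via multi-mapping reads
#'
#' Re-implementation of the repeat-region strategy: select reads whose
#' second-highest alignment score is at least `min_ratio` of the highest and
#' whose edit distance (primary and counted alternative alike) is at most
#' `max_edit`; for each such read the candidate interval runs from the
#' leftmost to the rightmost alignment position among the primary and the
#' tied second-best alternative hits. Candidates are clustered, clusters with
#' support below `min_support` are removed, survivors are merged at
#' `merge_frac` reciprocal overlap, and calls with coverage (by the selected
#' reads) below `min_coverage` are dropped.
#'
#' Alignment score is `aligned length - score_k * edit distance`; the
#' alternative-hit tags carry positions and edit distances, not aligner
#' scores, so score ratios are computed on this proxy.
#'
#' @param alignments alignment data.frame with XA-style alternative hits.
#' @param sample sample id stamped on the calls.
#' @param min_ratio second-best/best score ratio floor (inclusive).
#' @param max_edit maximum edit distance ("< 3" encoded as `<= 2`).
#' @param min_support minimum reads per candidate coordinate cluster.
#' @param merge_frac reciprocal-overlap fraction (0.8).
#' @param min_coverage coverage floor (kept when `>=`).
#' @param score_k edit-distance penalty per unit in the score proxy.
#' @return call data.frame as in [call_unique_circles()], mode `"repeat"`.
#'   The number of reads skipped for lack of alternative hits is attached as
#'   attribute `n_skipped`.
#' @export
call_repeat_circles <- function(alignments, sample = NA_character_,
                                min_ratio = 0.8, max_edit = 2L,
                                min_support = 20L, merge_frac = 0.8,
                                min_coverage = 0.8, score_k = 4) {
  a <- alignments[!alignments$secondary, , drop = FALSE]
  has_alt <- !is.na(a$xa) & nzchar(a$xa)
  n_skipped <- sum(!has_alt)
  a <- a[has_alt, , drop = FALSE]
  if (!nrow(a)) {
    out <- empty_calls()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  # flat parse of "contig,pos,strand,nm;..." alternative-hit lists
  entries <- strsplit(a$xa, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(a)), lengths(entries))
  flat <- unlist(entries, use.names = FALSE)
  alt_contig <- sub(",.*", "", flat)
  alt_pos <- as.integer(sub("^[^,]+,([0-9]+),.*", "\\1", flat))
  alt_nm <- as.integer(sub(".*,", "", flat))
  # second-best tier: alternative hits with minimal edit distance, same contig
  lo <- rep(Inf, nrow(a))
  agg_lo <- tapply(alt_nm, idx, min)
  lo[as.integer(names(agg_lo))] <- agg_lo
  tier <- alt_nm == lo[idx] & alt_contig == a$contig[idx]
  span <- matrix(NA_real_, nrow(a), 2)
  if (any(tier)) {
    mn <- tapply(alt_pos[tier], idx[tier], min)
    mx <- tapply(alt_pos[tier], idx[tier], max)
    span[as.integer(names(mn)), 1] <- mn
    span[as.integer(names(mx)), 2] <- mx
  }
  best <- a$aln_len - score_k * a$nm
  second <- a$aln_len - score_k * lo
  sel <- !is.na(span[, 1]) & a$nm <= max_edit & lo <= max_edit &
    best > 0 & (second / best) >= min_ratio
  s <- a[sel, , drop = FALSE]
  if (!nrow(s)) {
    out <- empty_calls()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  cand_start <- pmin(s$start, span[sel, 1])
  cand_end <- pmax(s$start + s$aln_len, span[sel, 2] + s$aln_len)
  cl <- cluster_intervals(s$contig, cand_start, cand_end, merge_frac)
  agg <- split(seq_along(cl), cl)
  calls <- do.call(rbind, lapply(agg, function(ix) data.frame(
    contig = s$contig[ix[1]],
    start = min(cand_start[ix]),
    end = max(cand_end[ix]),
    support = length(unique(s$qname[ix])),
    stringsAsFactors = FALSE)))
  calls <- calls[calls$support >= min_support, , drop = FALSE]
  if (nrow(calls)) calls <- merge_reciprocal(calls, merge_frac)
  calls$coverage_fraction <- vapply(seq_len(nrow(calls)), function(i)
    coverage_fraction(s, calls$contig[i], calls$start[i], calls$end[i],
                      min_mapq = 0L), numeric(1))
  calls <- calls[calls$coverage_fraction >= min_coverage, , drop = FALSE]
  out <- finish_calls(calls, "repeat", sample)
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_calls <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             name = character(0), support = integer(0), mode = character(0),
             coverage_fraction = numeric(0), sample = character(0),
             stringsAsFactors = FALSE)
}

finish_calls <- function(calls, mode, sample) {
  if (!nrow(calls)) return(empty_calls())
  calls <- calls[order(calls$contig, calls$start, calls$end), , drop = FALSE]
  data.frame(contig = calls$contig, start = as.integer(calls$start),
             end = as.integer(calls$end),
             name = sprintf("%s_%s_%03d", mode,
                            ifelse(is.na(sample), "call", sample),
                            seq_len(nrow(calls))),
             support = as.integer(calls$support), mode = mode,
             coverage_fraction = calls$coverage_fraction,
             sample = sample, stringsAsFactors = FALSE)
}

#' Detect both circle modes in one sample
#'
#' @param alignments the sample's coordinate-sorted alignments.
#' @param sample sample id.
#' @param unique_params,repeat_params named lists overriding detector defaults.
#' @return combined call data.frame.
#' @export
detect_circles <- function(alignments, sample = NA_character_,
                           unique_params = list(), repeat_params = list()) {
  ev <- extract_junction_evidence(alignments)
  u <- do.call(call_unique_circles,
               c(list(evidence = ev, alignments = alignments, sample = sample),
                 unique_params))
  r <- do.call(call_repeat_circles,
               c(list(alignments = alignments, sample = sample),
                 repeat_params))
  rbind(u, r)
}

#' Saturation of circle discovery under read subsampling
#'
#' Subsamples reads at the given fractions and re-runs a detector at each
#' depth. Subsampling is per-read-id Bernoulli thinning driven by one seeded
#' hash: read ids whose hash value is below the fraction are kept, so smaller
#' subsamples are nested inside every larger one and the curve is monotone
#' under monotone detection thresholds.
#'
#' @param alignments alignment data.frame.
#' @param detector function(alignments) returning a call data.frame.
#' @param fractions ascending fractions in (0, 1].
#' @param seed integer seed for the hash.
#' @return data.frame with fraction, n_reads, n_circles.
#' @export
saturation_curve <- function(alignments, detector,
                             fractions = seq(0.05, 1, by = 0.05), seed = 2L) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  if (is.unsorted(fractions)) stop("fractions must be ascending")
  u <- read_id_hash(unique(alignments$qname), seed)
  h <- u[alignments$qname]
  out <- lapply(fractions, function(f) {
    sub <- alignments[h <= f, , drop = FALSE]
    data.frame(fraction = f, n_reads = length(unique(sub$qname)),
               n_circles = nrow(detector(sub)))
  })
  do.call(rbind, out)
}

# deterministic, order-independent hash of read ids to [0, 1):
# polynomial string hash mod (2^31 - 1), mixed with the seed by LCG steps.
# All intermediate products stay below 2^53, so doubles are exact.
read_id_hash <- function(ids, seed) {
  m <- 2147483647
  alphabet <- c(" ", "_", ".", "-", ":", "/", as.character(0:9),
                LETTERS, letters)
  n <- if (length(ids)) max(nchar(ids)) else 0L
  h <- numeric(length(ids))
  for (i in seq_len(n)) {
    v <- match(substr(ids, i, i), alphabet, nomatch = 1L)
    h <- (h * 67 + v) %% m
  }
  h <- (h * 48271 + (seed %% m)) %% m
  h <- (h * 48271 + 1) %% m
  stats::setNames(h / m, ids)
}
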