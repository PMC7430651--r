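#' Match circle calls between two samples
#'
#' Two calls match when they are on the same contig and both their start and
#' end coordinates differ by at most the tolerance: 300 bp for unique-region
#' calls, 400 bp for repeat-region calls (the larger tolerance applies to a
#' mixed-mode pair). Each call is matched to at most one partner, greedily by
#' nearest start distance; matching is symmetric.
#'
#' @param calls_a,calls_b call data.frames (contig, start, end, mode).
#' @param tol_unique,tol_repeat coordinate tolerances in bp.
#' @return data.frame with columns `a`, `b` (row indices into the inputs).
#' @export
match_circles <- function(calls_a, calls_b, tol_unique = 300L,
                          tol_repeat = 400L) {
  if (!nrow(calls_a) || !nrow(calls_b))
    return(data.frame(a = integer(0), b = integer(0)))
  pairs <- list()
  for (i in seq_len(nrow(calls_a))) {
    tol_i <- ifelse(calls_b$mode == "repeat" | calls_a$mode[i] == "repeat",
                    tol_repeat, tol_unique)
    ok <- calls_b$contig == calls_a$contig[i] &
      abs(calls_b$start - calls_a$start[i]) <= tol_i &
      abs(calls_b$end - calls_a$end[i]) <= tol_i
    if (any(ok))
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = i, b = which(ok),
        d = abs(calls_b$start[ok] - calls_a$start[i]))
  }
  if (!length(pairs)) return(data.frame(a = integer(0), b = integer(0)))
  p <- do.call(rbind, pairs)
  p <- p[order(p$d, p$a, p$b), ]
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  keep <- logical(nrow(p))
  for (k in seq_len(nrow(p))) {
    if (!used_a[p$a[k]] && !used_b[p$b[k]]) {
      keep[k] <- TRUE
      used_a[p$a[k]] <- TRUE
      used_b[p$b[k]] <- TRUE
    }
  }
  out <- p[keep, c("a", "b")]
  out <- out[order(out$a), ]
  rownames(out) <- NULL
  out
}

#' Group circle calls across samples
#'
#' Single-linkage grouping over pairwise coordinate matches: calls from all
#' samples are pooled, every mutually matching pair (same criterion as
#' [match_circles()]) is an edge, and connected components become circle
#' groups. The canonical interval is the member-wise median of starts and
#' ends; the group mode is `repeat` if any member is. Single linkage plus a
#' median canonical interval makes the grouping invariant to sample order.
#'
#' @param calls combined call data.frame across samples (column `sample`).
#' @param tol_unique,tol_repeat tolerances as in [match_circles()].
#' @return list with `groups` (group_id, contig, start, end, mode, n_members)
#'   and `members` (group_id, plus every call column).
#' @export
group_circles <- function(calls, tol_unique = 300L, tol_repeat = 400L) {
  n <- nrow(calls)
  if (!n) {
    return(list(groups = data.frame(group_id = character(0),
                                    contig = character(0), start = integer(0),
                                    end = integer(0), mode = character(0),
                                    n_members = integer(0)),
                members = cbind(group_id = character(0), calls)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(calls$contig, calls$start, calls$end, calls$sample)
  x <- calls[ord, ]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (x$contig[j] != x$contig[i]) break
      if (x$start[j] - x$start[i] > tol_repeat) break
      tol <- if (x$mode[i] == "repeat" || x$mode[j] == "repeat")
        tol_repeat else tol_unique
      if (abs(x$start[j] - x$start[i]) <= tol &&
          abs(x$end[j] - x$end[i]) <= tol) {
        ri <- find(ord[i]); rj <- find(ord[j])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- match(root, unique(root[ord]))
  groups <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
    data.frame(contig = calls$contig[ix[1]],
               start = as.integer(round(stats::median(calls$start[ix]))),
               end = as.integer(round(stats::median(calls$end[ix]))),
               mode = if (any(calls$mode[ix] == "repeat")) "repeat" else "unique",
               n_members = length(ix), stringsAsFactors = FALSE)
  }))
  groups <- groups[order(groups$contig, groups$start, groups$end), ,
                   drop = FALSE]
  groups$group_id <- sprintf("grp%03d", seq_len(nrow(groups)))
  o <- order(groups$contig, groups$start, groups$end)
  key <- paste(groups$contig, groups$start, groups$end, groups$mode)
  comp_key <- vapply(split(seq_len(n), comp), function(ix)
    paste(calls$contig[ix[1]],
          as.integer(round(stats::median(calls$start[ix]))),
          as.integer(round(stats::median(calls$end[ix]))),
          if (any(calls$mode[ix] == "repeat")) "repeat" else "unique"),
    character(1))
  members <- cbind(group_id = groups$group_id[match(comp_key[comp], key)],
                   calls, stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(groups = groups[, c("group_id", "contig", "start", "end", "mode",
                           "n_members")],
       members = members)
}

# per-population class from a presence pattern over subpopulations
pattern_class <- function(young, progeny, aged) {
  if (young && progeny && aged) "I"
  else if (young && aged) "II"
  else if (young && progeny) "III"
  else if (young) "IV"
  else if (progeny || aged) "V"
  else NA_character_
}

CLASS_ORDER <- c(I = 3L, II = 2L, III = 2L, IV = 2L, V = 1L)

#' Classify circle inheritance across populations
#'
#' Within each population, a group's presence pattern over the young, progeny
#' and aged subpopulations maps to a class: I (all three), II (young and
#' aged), III (young and progeny), IV (young only) and V (de novo: only aged
#' and/or progeny). When different populations yield different classes, the
#' group takes the class of the highest order of representation
#' (I > \{II, III, IV\} > V); two different classes within the same order make
#' the group `ambiguous`, which downstream statistics exclude.
#'
#' @param grouping result of [group_circles()].
#' @param sheet sample sheet (sample, population, subpopulation).
#' @return the `groups` data.frame with added columns `class` and
#'   `per_population` (comma-separated per-population classes), plus the
#'   presence matrix as attribute `presence` (group x sample, logical).
#' @export
classify_inheritance <- function(grouping, sheet) {
  groups <- grouping$groups
  members <- grouping$members
  if (!nrow(groups)) {
    groups$class <- character(0)
    return(groups)
  }
  if (any(!members$sample %in% sheet$sample))
    stop("call sample missing from sheet: ",
         setdiff(members$sample, sheet$sample)[1])
  pres <- matrix(FALSE, nrow(groups), nrow(sheet),
                 dimnames = list(groups$group_id, sheet$sample))
  hit <- unique(members[, c("group_id", "sample")])
  pres[cbind(hit$group_id, hit$sample)] <- TRUE
  pops <- unique(sheet$population)
  cls <- character(nrow(groups))
  per_pop <- character(nrow(groups))
  for (g in seq_len(nrow(groups))) {
    pop_cls <- vapply(pops, function(p) {
      has <- function(sub) {
        smp <- sheet$sample[sheet$population == p & sheet$subpopulation == sub]
        length(smp) > 0L && any(pres[g, smp])
      }
      pattern_class(has("young"), has("progeny"), has("aged"))
    }, character(1))
    seen <- unique(pop_cls[!is.na(pop_cls)])
    if (!length(seen)) stop("group with zero members: ", groups$group_id[g])
    if (length(seen) == 1L) {
      cls[g] <- seen
    } else {
      top <- max(CLASS_ORDER[seen])
      top_cls <- unique(seen[CLASS_ORDER[seen] == top])
      cls[g] <- if (length(top_cls) == 1L) top_cls else "ambiguous"
    }
    per_pop[g] <- paste(ifelse(is.na(pop_cls), ".", pop_cls), collapse = ",")
  }
  groups$class <- cls
  groups$per_population <- per_pop
  attr(groups, "presence") <- pres
  groups
}

#' Unfiltered rescue re-intersection of class IV circles
#'
#' Class IV means a circle was seen in young but not in aged samples under
#' the standard detection filters. To rule out that the filters themselves
#' caused the loss, detection is re-run on the aged samples with all support
#' and coverage filters disabled, and each class IV group is re-intersected
#' with those unfiltered calls under the standard coordinate tolerances. The
#' reported fraction is the share of class IV groups with no read evidence at
#' all in any aged sample.
#'
#' @param class4_groups classified groups with `class == "IV"` (canonical
#'   contig/start/end/mode columns).
#' @param aged_alignments named list of alignment data.frames, aged samples.
#' @param tol_unique,tol_repeat matching tolerances.
#' @return list: `fraction_no_evidence` (NA when there are no class IV
#'   groups), `n_class4`, `n_rescued`, and per-group logical `rescued`.
#' @export
rescue_unfiltered_class4 <- function(class4_groups, aged_alignments,
                                     tol_unique = 300L, tol_repeat = 400L) {
  n <- nrow(class4_groups)
  if (!n)
    return(list(fraction_no_evidence = NA_real_, n_class4 = 0L,
                n_rescued = 0L, rescued = logical(0)))
  unfiltered <- lapply(names(aged_alignments), function(s) {
    al <- aged_alignments[[s]]
    ev <- extract_junction_evidence(al)
    u <- call_unique_circles(ev, al, sample = s, min_support = 1L,
                             min_coverage = 0)
    r <- call_repeat_circles(al, sample = s, min_support = 1L,
                             min_coverage = 0)
    rbind(u, r)
  })
  unfiltered <- do.call(rbind, unfiltered)
  rescued <- logical(n)
  if (nrow(unfiltered)) {
    m <- match_circles(class4_groups, unfiltered, tol_unique, tol_repeat)
    rescued[unique(m$a)] <- TRUE
    # greedy 1:1 matching can starve a group when several class IV groups hit
    # the same unfiltered call; any qualifying pair counts as evidence here
    for (i in which(!rescued)) {
      tol_i <- ifelse(unfiltered$mode == "repeat" |
                        class4_groups$mode[i] == "repeat",
                      tol_repeat, tol_unique)
      rescued[i] <- any(unfiltered$contig == class4_groups$contig[i] &
                          abs(unfiltered$start - class4_groups$start[i]) <= tol_i &
                          abs(unfiltered$end - class4_groups$end[i]) <= tol_i)
    }
  }
  list(fraction_no_evidence = sum(!rescued) / n, n_class4 = n,
       n_rescued = sum(rescued), rescued = rescued)
}

#' De novo circle formation rate per cell division
#'
#' The number of de novo (class V) circles detected in a population's aged
#' subpopulation divided by the number of recovered cells times the number
#' of divisions the aged mothers underwent (~15).
#'
#' @param n_denovo de novo circle count (scalar or per-population vector).
#' @param n_cells recovered cell count (recycled to match).
#' @param n_divisions divisions undergone by the aged cells.
#' @return list with per-population `rate`, and `median` and `range` across
#'   populations.
#' @export
de_novo_rate <- function(n_denovo, n_cells, n_divisions = 15) {
  if (any(n_cells <= 0)) stop("n_cells must be > 0")
  if (n_divisions <= 0) stop("n_divisions must be > 0")
  rate <- n_denovo / (n_cells * n_divisions)
  list(rate = rate, median = stats::median(rate), range = range(rate))
}
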