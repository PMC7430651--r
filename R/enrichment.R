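#' Annotate circle groups with genomic features
#'
#' A feature is present on a circle when its interval overlaps the circle's
#' canonical interval by at least one base (half-open coordinates; an
#' abutting feature does not overlap). Replication origins use the same
#' any-overlap rule — non-exact overlap is allowed because origin
#' annotations have limited resolution.
#'
#' @param groups group table (group_id, contig, start, end).
#' @param features feature table (kind, contig, start, end, name); kinds must
#'   come from the closed vocabulary.
#' @return logical matrix, groups x feature kinds.
#' @export
annotate_features <- function(groups, features) {
  bad <- setdiff(unique(features$kind), FEATURE_KINDS)
  if (length(bad)) stop("unknown feature kind: ", paste(bad, collapse = ", "))
  kinds <- intersect(FEATURE_KINDS, unique(features$kind))
  gr <- GenomicRanges::GRanges(groups$contig,
                               IRanges::IRanges(groups$start + 1L, groups$end))
  fr <- GenomicRanges::GRanges(features$contig,
                               IRanges::IRanges(features$start + 1L,
                                                features$end))
  hits <- GenomicRanges::findOverlaps(gr, fr)
  m <- matrix(FALSE, nrow(groups), length(kinds),
              dimnames = list(groups$group_id, kinds))
  if (length(hits)) {
    k <- features$kind[S4Vectors::subjectHits(hits)]
    m[cbind(S4Vectors::queryHits(hits), match(k, kinds))] <- TRUE
  }
  m
}

#' Scan a circle sequence for an exact motif match
#'
#' Exact substring search over the circle's reference sequence, extended by a
#' junction window of `motif length - 1` bases wrapping from the end back to
#' the start — the molecule is circular, so a motif can span the junction.
#' Both strands are scanned. Set `wrap = FALSE` to scan the linear sequence
#' only.
#'
#' @param sequence circle sequence (A/C/G/T string).
#' @param motif motif string over A/C/G/T; empty is an error.
#' @param wrap scan across the circular junction.
#' @param both_strands also scan the reverse complement.
#' @return TRUE when the motif occurs.
#' @export
scan_motif <- function(sequence, motif, wrap = TRUE, both_strands = TRUE) {
  if (!nzchar(motif)) stop("empty motif")
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
  subject <- toupper(sequence)
  if (wrap && nchar(motif) > 1L)
    subject <- paste0(subject, substr(subject, 1L, nchar(motif) - 1L))
  if (grepl(motif, subject, fixed = TRUE)) return(TRUE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    return(grepl(rc, subject, fixed = TRUE))
  }
  FALSE
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the two-sided convention of summing the
#' probabilities of all margin-fixed tables whose point probability does not
#' exceed the observed table's. The reported odds ratio is the sample odds
#' ratio `(a*d)/(b*c)`, not the conditional MLE. A table with a zero margin
#' has p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts (feature+/- x group1/2).
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  p <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) 1
  else stats::fisher.test(m, alternative = "two.sided")$p.value
  list(odds_ratio = (a * d) / (b * c), p = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment within a test family
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals)))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null when the combined sample size is at
#' most `exact_max` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max combined-size cutoff for the exact test.
#' @return two-sided p-value.
#' @export
wilcoxon_two_sided <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("empty group")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact)$p.value)
}

#' Feature and motif overrepresentation between inheritance class groups
#'
#' For every genomic feature kind and every cis-element motif, builds the
#' 2x2 table of presence against class grouping (classes I+II versus
#' III+IV; class V and ambiguous circles are excluded upstream), runs the
#' two-sided Fisher test, and BH-adjusts the genomic-feature and cis-element
#' families independently. Circle sizes between the two class groups are
#' compared with the two-sided Wilcoxon test.
#'
#' @param classes per-group inheritance class, aligned with `presence` rows;
#'   must all be in I, II, III, IV.
#' @param presence logical matrix groups x features ([annotate_features()]).
#' @param motif_presence optional logical matrix groups x motifs
#'   (family `cis_element`).
#' @param lengths optional circle lengths for the size comparison.
#' @return list: `results` data.frame (feature, family, a, b, c, d,
#'   odds_ratio, p, adjusted_p) and `size_test` (Wilcoxon p or NA).
#' @export
enrichment_screen <- function(classes, presence, motif_presence = NULL,
                              lengths = NULL) {
  if (!all(classes %in% c("I", "II", "III", "IV")))
    stop("classes must be I, II, III or IV (exclude V and ambiguous)")
  in12 <- classes %in% c("I", "II")
  if (!any(in12) || all(in12)) stop("empty class group")
  one_family <- function(mat, family) {
    if (is.null(mat) || !ncol(mat)) return(NULL)
    rows <- lapply(colnames(mat), function(f) {
      a <- sum(mat[in12, f]); b <- sum(in12) - a
      cc <- sum(mat[!in12, f]); dd <- sum(!in12) - cc
      ft <- fisher_two_sided(a, b, cc, dd)
      data.frame(feature = f, family = family, a = a, b = b, c = cc, d = dd,
                 odds_ratio = ft$odds_ratio, p = ft$p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$adjusted_p <- bh_adjust(out$p)
    out
  }
  results <- rbind(one_family(presence, "genomic_feature"),
                   one_family(motif_presence, "cis_element"))
  size_test <- NA_real_
  if (!is.null(lengths))
    size_test <- wilcoxon_two_sided(lengths[in12], lengths[!in12])
  list(results = results, size_test = size_test)
}
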