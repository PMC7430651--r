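#' Count reads over circle groups
#'
#' For every circle group and sample, counts reads whose aligned segment
#' overlaps the canonical interval by at least one base and whose mapping
#' quality is at least `min_mapq` (unambiguous alignment). Groups on a
#' tandem-array contig region are counted with no mapping-quality filter:
#' their reads are multi-mapping by construction of the repeat structure.
#'
#' @param groups group table (group_id, contig, start, end, mode).
#' @param alignments named list of alignment data.frames, one per sample.
#' @param min_mapq quality floor for unambiguous counting.
#' @param no_filter_groups group_ids exempt from the quality filter (defaults
#'   to groups whose mode is `repeat`).
#' @return integer matrix groups x samples with class `ecc_counts` attributes.
#' @export
count_matrix <- function(groups, alignments, min_mapq = 20L,
                         no_filter_groups = NULL) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list keyed by sample")
  if (is.null(no_filter_groups))
    no_filter_groups <- groups$group_id[groups$mode == "repeat"]
  m <- matrix(0L, nrow(groups), length(alignments),
              dimnames = list(groups$group_id, names(alignments)))
  for (s in names(alignments)) {
    a <- alignments[[s]]
    a <- a[!a$secondary, , drop = FALSE]
    for (g in seq_len(nrow(groups))) {
      mq <- if (groups$group_id[g] %in% no_filter_groups) 0L else min_mapq
      m[g, s] <- sum(a$contig == groups$contig[g] & a$mapq >= mq &
                       a$start < groups$end[g] &
                       (a$start + a$aln_len) > groups$start[g])
    }
  }
  m
}

#' Median-of-ratios size factors
#'
#' The normalization of count matrices by the median of ratios: reference
#' rows are rows with strictly positive counts in every sample; for each row
#' the geometric mean across samples is taken; a sample's size factor is the
#' median, over reference rows, of the ratio of its count to the row
#' geometric mean. Robust to a few rows with very large differential
#' abundance (here, rDNA circles).
#'
#' @param counts numeric matrix, groups x samples.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no reference row with nonzero counts in every sample; ",
         "pseudo-reference fallback is off")
  r <- counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(r)))
  apply(r / geo, 2, stats::median)
}

#' Normalized and log10 views of a count matrix
#'
#' `normalize_counts` divides each sample's column by its size factor;
#' `normalize_log10` applies `log10(normalized + pseudocount)`.
#'
#' @param counts matrix groups x samples.
#' @param size_factors per-sample factors (defaults to median of ratios).
#' @param pseudocount added before the log (zeros map to `log10(1) = 0`).
#' @return numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts,
                             size_factors = size_factors_median_of_ratios(counts)) {
  if (any(size_factors <= 0)) stop("size factors must be > 0")
  sweep(counts, 2, size_factors, "/")
}

#' @rdname normalize_counts
#' @export
normalize_log10 <- function(counts,
                            size_factors = size_factors_median_of_ratios(counts),
                            pseudocount = 1) {
  log10(normalize_counts(counts, size_factors) + pseudocount)
}

#' Keep circles detected in at least `min_samples` samples
#'
#' Detection means a nonzero raw count (reads counted over already-called
#' coordinates). Rows failing the threshold are removed.
#'
#' @param counts matrix groups x samples (raw counts).
#' @param min_samples recurrence threshold.
#' @return the filtered matrix.
#' @export
recurrence_filter <- function(counts, min_samples = 2L) {
  counts[rowSums(counts > 0) >= min_samples, , drop = FALSE]
}

#' PCA and hierarchical clustering of circle profiles
#'
#' PCA treats samples as observations and circle groups as variables,
#' centered and scaled to unit variance. Hierarchical clustering uses
#' Manhattan (L1) distance with average linkage (UPGMA), for both rows
#' (groups) and columns (samples).
#'
#' @param logmat log-transformed normalized matrix, groups x samples
#'   (>= 2 rows and >= 2 columns).
#' @return list: `pca` (a `prcomp`; `$x` holds per-sample scores),
#'   `row_hclust`, `col_hclust`.
#' @export
cluster_profiles <- function(logmat) {
  if (nrow(logmat) < 2L || ncol(logmat) < 2L)
    stop("need >= 2 rows and >= 2 columns")
  v <- apply(logmat, 1, stats::var)
  if (any(v == 0))
    stop("constant row under scaling: ",
         paste(rownames(logmat)[v == 0], collapse = ", "))
  pca <- stats::prcomp(t(logmat), center = TRUE, scale. = TRUE)
  list(pca = pca,
       row_hclust = stats::hclust(stats::dist(logmat, method = "manhattan"),
                                  method = "average"),
       col_hclust = stats::hclust(stats::dist(t(logmat), method = "manhattan"),
                                  method = "average"))
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object.
#' @param path optional file to write.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}

#' Log10 fold change between aged and young counts
#'
#' `log10((aged + pseudocount) / (young + pseudocount))` on matched
#' normalized counts; antisymmetric in its arguments.
#'
#' @param aged,young matched numeric vectors of normalized counts.
#' @param pseudocount added to both sides.
#' @return numeric vector of log10 fold changes.
#' @export
log_fold_change <- function(aged, young, pseudocount = 1) {
  log10((aged + pseudocount) / (young + pseudocount))
}

#' Spike-in normalized abundance of rDNA, Y' and other circles
#'
#' Counts reads on (i) the spike-in plasmid contigs, (ii) the Y' locus
#' intervals, (iii) the rDNA locus (both repeat loci without a quality
#' filter, due to their duplicated structure) and (iv) the other called
#' circle intervals (quality >= `min_mapq`), then divides categories
#' (ii)-(iv) by the plasmid read sum.
#'
#' @param alignments named list of alignment data.frames (per sample).
#' @param plasmid_names contig names whose reads form the denominator.
#' @param rdna_interval list(contig, start, end) of the rDNA locus.
#' @param yprime_intervals data.frame(contig, start, end) of Y' loci.
#' @param other_groups group table of the remaining circles.
#' @param min_mapq quality floor for the "other" category.
#' @return data.frame per sample: read counts per category and the three
#'   plasmid-normalized ratios.
#' @export
spike_in_levels <- function(alignments, plasmid_names, rdna_interval,
                            yprime_intervals, other_groups, min_mapq = 20L) {
  count_win <- function(a, contig, start, end, mq) {
    sum(a$contig == contig & a$mapq >= mq & a$start < end &
          (a$start + a$aln_len) > start)
  }
  rows <- lapply(names(alignments), function(s) {
    a <- alignments[[s]]
    a <- a[!a$secondary, , drop = FALSE]
    plasmid <- sum(a$contig %in% plasmid_names)
    if (plasmid == 0) stop("zero plasmid reads in sample ", s)
    rdna <- count_win(a, rdna_interval$contig, rdna_interval$start,
                      rdna_interval$end, 0L)
    yp <- sum(vapply(seq_len(nrow(yprime_intervals)), function(i)
      count_win(a, yprime_intervals$contig[i], yprime_intervals$start[i],
                yprime_intervals$end[i], 0L), numeric(1)))
    other <- sum(vapply(seq_len(nrow(other_groups)), function(i)
      count_win(a, other_groups$contig[i], other_groups$start[i],
                other_groups$end[i], min_mapq), numeric(1)))
    data.frame(sample = s, plasmid_reads = plasmid, rdna_reads = rdna,
               yprime_reads = yp, other_reads = other,
               rdna_ratio = rdna / plasmid, yprime_ratio = yp / plasmid,
               other_ratio = other / plasmid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of circle-derived reads on the rDNA locus
#'
#' `100 * rDNA reads / (rDNA reads + reads on other called circles)`.
#' The rDNA locus is counted without a quality filter; other circles with
#' quality >= `min_mapq`.
#'
#' @param alignments one sample's alignment data.frame.
#' @param rdna_interval list(contig, start, end).
#' @param other_groups group table of non-rDNA circles (column `mode`;
#'   repeat-mode groups are counted without a quality filter).
#' @param min_mapq quality floor for unique-mode circles.
#' @return percentage, or NA when no circle-derived reads exist.
#' @export
rdna_fraction <- function(alignments, rdna_interval, other_groups,
                          min_mapq = 20L) {
  a <- alignments[!alignments$secondary, , drop = FALSE]
  rdna <- sum(a$contig == rdna_interval$contig &
                a$start < rdna_interval$end &
                (a$start + a$aln_len) > rdna_interval$start)
  mq <- ifelse(other_groups$mode == "repeat", 0L, min_mapq)
  other <- sum(vapply(seq_len(nrow(other_groups)), function(i)
    sum(a$contig == other_groups$contig[i] & a$mapq >= mq[i] &
          a$start < other_groups$end[i] &
          (a$start + a$aln_len) > other_groups$start[i]), numeric(1)))
  if (rdna + other == 0) return(NA_real_)
  100 * rdna / (rdna + other)
}
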