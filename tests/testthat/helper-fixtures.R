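# shared fixtures and independent oracles -----------------------------------

# hand-built alignment records with sensible defaults
make_align <- function(qname, contig, start, aln_len = 100L, strand = "+",
                       mapq = 60L, clip_left = 0L, clip_right = 0L,
                       sa_contig = NA_character_, sa_pos = NA_integer_,
                       sa_strand = NA_character_,
                       mate_contig = NA_character_, mate_pos = NA_integer_,
                       mate_strand = NA_character_, nm = 0L,
                       xa = NA_character_, secondary = FALSE) {
  data.frame(qname = qname, contig = contig, start = as.integer(start),
             aln_len = as.integer(aln_len), strand = strand,
             mapq = as.integer(mapq), clip_left = as.integer(clip_left),
             clip_right = as.integer(clip_right), sa_contig = sa_contig,
             sa_pos = as.integer(sa_pos), sa_strand = sa_strand,
             mate_contig = mate_contig, mate_pos = as.integer(mate_pos),
             mate_strand = mate_strand, nm = as.integer(nm), xa = xa,
             secondary = secondary, stringsAsFactors = FALSE)
}

bind_aligns <- function(...) {
  out <- do.call(rbind, list(...))
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  out
}

# memoized heavy fixtures ----------------------------------------------------
.ecc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ecc_cache))
    assign(key, force(expr), envir = .ecc_cache)
  get(key, envir = .ecc_cache)
}

# full default-conditions pipeline run (the study-conditions cohort)
full_run <- function() cached("full_run", {
  suppressMessages(run_pipeline(default_config(
    seed = 1L, outdir = file.path(tempdir(), "ecc_full_run"))))
})

# a reduced cohort for fast property tests (same structure, smaller)
small_design <- function() {
  d <- default_cohort_design()
  d$class_counts <- c(I = 0L, II = 0L, III = 1L, IV = 8L, V = 2L)
  d$rdna$abundance <- 20
  d$library_size <- 9000L
  d
}

small_world <- function() cached("small_world", {
  g <- build_toy_genome(seed = 3L)
  co <- plan_circle_cohort(g, small_design(), make_sample_sheet(), seed = 3L)
  al <- simulate_cohort(g, co, seed = 3L)
  list(genome = g, cohort = co, alignments = al,
       truth = cohort_truth_table(co))
})

# independent oracles --------------------------------------------------------

# exact two-sided Fisher p by enumeration of all margin-fixed tables
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(xs, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)),
    numeric(1))
  p_obs <- pr[match(a, xs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# exact two-sided rank-sum p by full enumeration of group assignments
wilcox_enum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, function(ix) sum(seq_len(n)[ix])) -
    length(x) * (length(x) + 1) / 2
  lower <- mean(ws <= w_obs)
  upper <- mean(ws >= w_obs)
  min(1, 2 * min(lower, upper))
}

# fixed-point reciprocal merging by exhaustive pair scanning (order-free:
# always merges the lexicographically first qualifying pair)
merge_oracle <- function(iv, frac) {
  x <- iv[order(iv$start, iv$end), , drop = FALSE]
  repeat {
    n <- nrow(x)
    hit <- NULL
    for (i in seq_len(max(0, n - 1))) {
      for (j in (i + 1):n) {
        ov <- min(x$end[i], x$end[j]) - max(x$start[i], x$start[j])
        if (ov > 0 && ov / (x$end[i] - x$start[i]) >= frac &&
            ov / (x$end[j] - x$start[j]) >= frac) {
          hit <- c(i, j); break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    x$start[hit[1]] <- min(x$start[hit]); x$end[hit[1]] <- max(x$end[hit])
    x <- x[-hit[2], , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

# per-position coverage counting
coverage_oracle <- function(alignments, contig, start, end, min_mapq = 20L) {
  pos <- rep(FALSE, end - start)
  a <- alignments[alignments$contig == contig & alignments$mapq >= min_mapq, ]
  for (i in seq_len(nrow(a))) {
    s <- max(a$start[i], start); e <- min(a$start[i] + a$aln_len[i], end)
    if (e > s) pos[(s - start + 1):(e - start)] <- TRUE
  }
  mean(pos)
}
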