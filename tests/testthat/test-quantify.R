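test_that("read counting honors overlap and mapping-quality rules", {
  g <- data.frame(group_id = c("g1", "g2"), contig = "chr1",
                  start = c(1000L, 5000L), end = c(2000L, 6000L),
                  mode = c("unique", "repeat"), stringsAsFactors = FALSE)
  al <- list(sA = bind_aligns(
    make_align(paste0("a", 1:7), "chr1", seq(1100L, 1700L, by = 100L),
               mapq = 30L),
    make_align("low1", "chr1", 1500L, mapq = 10L),
    make_align("edge", "chr1", 2000L),              # abuts, does not overlap
    make_align(paste0("m", 1:4), "chr1", seq(5100L, 5400L, by = 100L),
               mapq = 0L)))
  cm <- count_matrix(g, al)
  expect_equal(cm["g1", "sA"], 7L)    # quality >= 20 only
  expect_equal(cm["g2", "sA"], 4L)    # repeat group: no quality filter
  cm0 <- count_matrix(g, al, no_filter_groups = character(0))
  expect_equal(cm0["g2", "sA"], 0L)   # with the filter the multireads vanish
})

test_that("median-of-ratios size factors match closed forms", {
  m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- size_factors_median_of_ratios(m)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  same <- cbind(A = c(5, 9, 2), B = c(5, 9, 2))
  expect_equal(unname(size_factors_median_of_ratios(same)), c(1, 1))
  # rows containing a zero leave the reference set
  with_zero <- rbind(m, c(0, 1000))
  expect_equal(size_factors_median_of_ratios(with_zero),
               size_factors_median_of_ratios(m))
  all_zero_somewhere <- cbind(A = c(0, 3), B = c(4, 0))
  expect_error(size_factors_median_of_ratios(all_zero_somewhere),
               "reference row")
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  # with an odd number of reference rows the median needs no interpolation
  # and the two implementations agree exactly; with an even count this
  # package takes the arithmetic midpoint of the central ratios where DESeq2
  # interpolates on the log scale
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rpois(54, lambda = 50) + 1, nrow = 9)
    colnames(m) <- paste0("s", 1:6)
    expect_equal(size_factors_median_of_ratios(m),
                 DESeq2::estimateSizeFactorsForMatrix(m))
  }
})

test_that("scaling one sample scales its relative factor and preserves
           normalized counts up to one global constant", {
  # the row geometric means absorb c^(1/m), so the scaled sample's factor
  # grows by c relative to every other sample, and all normalized counts are
  # rescaled by one common constant (their ratios are unchanged)
  set.seed(13)
  for (i in 1:1000) {
    m <- matrix(rpois(12, lambda = 40) + 1, nrow = 4,
                dimnames = list(NULL, c("A", "B", "C")))
    c_scale <- sample(c(2, 3, 10), 1)
    m2 <- m
    m2[, "B"] <- m2[, "B"] * c_scale
    sf1 <- size_factors_median_of_ratios(m)
    sf2 <- size_factors_median_of_ratios(m2)
    expect_equal(sf2[["B"]] / sf2[["A"]],
                 c_scale * sf1[["B"]] / sf1[["A"]])
    n1 <- normalize_counts(m, sf1)
    n2 <- normalize_counts(m2, sf2)
    expect_equal(n2, n1 * (n2[1, 1] / n1[1, 1]))
  }
})

test_that("log transform anchors and monotonicity", {
  m <- cbind(A = c(0, 99, 5), B = c(0, 99, 7))
  sf <- c(A = 1, B = 1)
  lg <- normalize_log10(m, sf)
  expect_equal(unname(lg[1, "A"]), 0)
  expect_equal(unname(lg[2, "A"]), 2)
  expect_true(lg[3, "B"] > lg[3, "A"])
})

test_that("recurrence filter keeps rows detected in >= 2 samples", {
  m <- rbind(one = c(5, 0, 0), two = c(3, 1, 0), all = c(1, 1, 1))
  out <- recurrence_filter(m)
  expect_equal(rownames(out), c("two", "all"))
  empty <- recurrence_filter(m[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("profile clustering uses Manhattan distance and average linkage", {
  m <- rbind(g1 = c(0, 3, 0.5), g2 = c(0, 4, 0.2), g3 = c(1, 0, 1.3))
  colnames(m) <- c("s1", "s2", "s3")
  # duplicated sample merges at height 0
  m2 <- cbind(m, s4 = m[, "s2"])
  pr <- cluster_profiles(m2)
  d <- as.matrix(dist(t(m2), method = "manhattan"))
  expect_equal(d["s2", "s4"], 0)
  expect_equal(min(pr$col_hclust$height), 0)
  # L1 arithmetic: (0,0) vs (3,4) -> 7
  expect_equal(unname(as.matrix(dist(rbind(c(0, 0), c(3, 4)),
                                     method = "manhattan"))[1, 2]), 7)
  # PCA scores are invariant (up to sign) under sample reordering
  p1 <- cluster_profiles(m)$pca
  perm <- c("s3", "s1", "s2")
  p2 <- cluster_profiles(m[, perm])$pca
  for (k in 1:2) {
    v1 <- p1$x[perm, k]; v2 <- p2$x[, k]
    expect_true(isTRUE(all.equal(v1, v2, tolerance = 1e-8)) ||
                  isTRUE(all.equal(v1, -v2, tolerance = 1e-8)))
  }
  # constant row under scaling is an error naming the row
  bad <- rbind(flat = c(1, 1, 1), g2 = c(0, 4, 0.2))
  colnames(bad) <- colnames(m)
  expect_error(cluster_profiles(bad), "flat")
})

test_that("log fold change anchors and antisymmetry", {
  expect_equal(log_fold_change(5, 5), 0)
  expect_equal(log_fold_change(999, 0), 3)
  x <- c(3, 10, 0); y <- c(8, 2, 7)
  expect_equal(log_fold_change(x, y), -log_fold_change(y, x))
})

test_that("spike-in ratios are plasmid-normalized and scale-invariant", {
  g <- build_toy_genome(seed = 21)
  mk <- function(n_rdna, n_plasmid) {
    td <- g$tandem
    bind_aligns(
      make_align(paste0("r", 1:n_rdna), td$contig,
                 td$start + seq_len(n_rdna) %% 1000L, mapq = 0L),
      make_align(paste0("p", 1:n_plasmid), "pSH63",
                 seq_len(n_plasmid) %% 1000L))
  }
  other <- data.frame(group_id = "o1", contig = "chrU1", start = 100L,
                      end = 600L, mode = "unique", stringsAsFactors = FALSE)
  td <- g$tandem
  rep1 <- spike_in_levels(list(s = mk(50000L, 1000L)),
                          c("pUC19_yEGFP", "pSH63", "p4339", "pRS316"),
                          list(contig = td$contig, start = td$start,
                               end = td$end),
                          g$dispersed, other)
  expect_equal(rep1$rdna_ratio, 50)
  rep2 <- spike_in_levels(list(s = mk(100000L, 2000L)),
                          c("pUC19_yEGFP", "pSH63", "p4339", "pRS316"),
                          list(contig = td$contig, start = td$start,
                               end = td$end),
                          g$dispersed, other)
  expect_equal(rep2$rdna_ratio, rep1$rdna_ratio)
  expect_error(
    spike_in_levels(list(s = mk(10L, 1000L)[1:10, ]), "pRS316",
                    list(contig = td$contig, start = td$start, end = td$end),
                    g$dispersed, other),
    "zero plasmid reads")
})

test_that("rDNA read percentage arithmetic", {
  g <- build_toy_genome(seed = 21)
  td <- g$tandem
  rdna_iv <- list(contig = td$contig, start = td$start, end = td$end)
  other <- data.frame(group_id = "o1", contig = "chrU1", start = 1000L,
                      end = 2000L, mode = "unique", stringsAsFactors = FALSE)
  all_rdna <- make_align(paste0("r", 1:10), td$contig,
                         td$start + (1:10) * 7L, mapq = 0L)
  expect_equal(rdna_fraction(all_rdna, rdna_iv, other), 100)
  half <- bind_aligns(all_rdna,
                      make_align(paste0("o", 1:10), "chrU1",
                                 1100L + (1:10) * 3L))
  expect_equal(rdna_fraction(half, rdna_iv, other), 50)
  none <- make_align("x", "chrU2", 5L)
  expect_true(is.na(rdna_fraction(none, rdna_iv, other)))
})
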