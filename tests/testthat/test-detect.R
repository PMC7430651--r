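test_that("junction evidence intervals span the two circle boundaries", {
  # soft-clipped at 2000, clip maps back to 1000 -> evidence [1000, 2000)
  a <- make_align("r1", "chr1", 1930L, aln_len = 70L, clip_right = 30L,
                  sa_contig = "chr1", sa_pos = 1000L, sa_strand = "+")
  ev <- extract_junction_evidence(a)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "split")
  expect_equal(c(ev$start, ev$end), c(1000L, 2000L))

  # fully aligned concordant (inward) pair -> nothing
  pair <- bind_aligns(
    make_align("p1", "chr1", 1100L, strand = "+", mate_contig = "chr1",
               mate_pos = 1300L, mate_strand = "-"),
    make_align("p1", "chr1", 1300L, strand = "-", mate_contig = "chr1",
               mate_pos = 1100L, mate_strand = "+"))
  expect_equal(nrow(extract_junction_evidence(pair)), 0L)

  # outward pair at 1100/1900 -> discordant evidence containing [1100, 1900)
  out <- bind_aligns(
    make_align("d1", "chr1", 1100L, strand = "-", mate_contig = "chr1",
               mate_pos = 1900L, mate_strand = "+"),
    make_align("d1", "chr1", 1900L, strand = "+", mate_contig = "chr1",
               mate_pos = 1100L, mate_strand = "-"))
  ev <- extract_junction_evidence(out)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "discordant")
  expect_lte(ev$start, 1100L)
  expect_gte(ev$end, 1900L)
})

test_that("unsorted alignments are rejected with the offending record", {
  a <- rbind(make_align("r2", "chr1", 500L), make_align("r1", "chr1", 100L))
  expect_error(extract_junction_evidence(a), "not coordinate-sorted.*r1")
})

test_that("unique calling enforces the support and coverage cuts", {
  mk_circle_sample <- function(n_junction, tile_to = 2000L) {
    jr <- lapply(seq_len(n_junction), function(i)
      make_align(paste0("j", i), "chr1", 1900L, aln_len = 100L,
                 clip_right = 40L, sa_contig = "chr1", sa_pos = 1000L,
                 sa_strand = "+"))
    tiles <- lapply(seq(1000L, tile_to - 100L, by = 50L), function(p)
      make_align(paste0("t", p), "chr1", p))
    do.call(bind_aligns, c(jr, tiles))
  }
  # 10 junction reads, fully covered -> one call with support 10
  al <- mk_circle_sample(10L)
  calls <- call_unique_circles(extract_junction_evidence(al), al, "s")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 10L)
  expect_equal(c(calls$start, calls$end), c(1000L, 2000L))

  # exactly 4 supporting reads -> below "more than 4" -> no call
  al4 <- mk_circle_sample(4L)
  expect_equal(nrow(call_unique_circles(extract_junction_evidence(al4),
                                        al4, "s")), 0L)
  # 5 reads -> call
  al5 <- mk_circle_sample(5L)
  expect_equal(nrow(call_unique_circles(extract_junction_evidence(al5),
                                        al5, "s")), 1L)

  # 10 reads but only half the interval covered -> no call
  half <- mk_circle_sample(10L, tile_to = 1400L)
  expect_equal(nrow(call_unique_circles(extract_junction_evidence(half),
                                        half, "s")), 0L)

  # empty evidence -> empty calls
  expect_equal(nrow(call_unique_circles(extract_junction_evidence(
    make_align("x", "chr1", 1L)), make_align("x", "chr1", 1L), "s")), 0L)
})

test_that("reciprocal merging follows the fraction semantics exactly", {
  two <- data.frame(contig = "c", start = c(0L, 50L), end = c(100L, 150L),
                    support = c(3L, 4L), stringsAsFactors = FALSE)
  m <- merge_reciprocal(two, 0.5)   # each overlap 50/100 = 0.5 -> merge
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end, m$support), c(0L, 150L, 7L))
  m8 <- merge_reciprocal(two, 0.8)  # 0.5 < 0.8 -> unchanged
  expect_equal(nrow(m8), 2L)

  disjoint <- data.frame(contig = "c", start = c(0L, 500L),
                         end = c(100L, 600L), support = c(1L, 1L))
  expect_equal(nrow(merge_reciprocal(disjoint, 0.5)), 2L)

  expect_error(merge_reciprocal(two, 0), "min_frac")
  expect_error(merge_reciprocal(two, 1.5), "min_frac")
})

test_that("merging is idempotent, order-invariant and matches brute force", {
  set.seed(42)
  for (trial in 1:1000) {
    n <- sample(2:10, 1)
    start <- sample(0:500, n, replace = TRUE)
    len <- sample(20:200, n, replace = TRUE)
    iv <- data.frame(contig = "c", start = start, end = start + len,
                     support = rep(1L, n), stringsAsFactors = FALSE)
    frac <- sample(c(0.5, 0.8), 1)
    merged <- merge_reciprocal(iv, frac)
    # idempotent
    again <- merge_reciprocal(merged, frac)
    expect_equal(merged[c("start", "end")], again[c("start", "end")])
    # order-invariant
    shuf <- merge_reciprocal(iv[sample.int(n), ], frac)
    expect_equal(merged[c("start", "end", "support")],
                 shuf[c("start", "end", "support")])
    # equals the exhaustive-pair-scan oracle
    oracle <- merge_oracle(iv[c("start", "end")], frac)
    expect_equal(merged$start, oracle$start)
    expect_equal(merged$end, oracle$end)
  }
})

test_that("coverage fraction counts covered positions", {
  tiles <- do.call(bind_aligns, lapply(seq(0L, 900L, by = 100L), function(p)
    make_align(paste0("t", p), "chr1", p)))
  expect_equal(coverage_fraction(tiles, "chr1", 0L, 1000L), 1.0)
  one <- make_align("r", "chr1", 0L, aln_len = 500L)
  expect_equal(coverage_fraction(one, "chr1", 0L, 1000L), 0.5)
  expect_equal(coverage_fraction(one, "chr2", 0L, 1000L), 0.0)
  expect_error(coverage_fraction(one, "chr1", 10L, 10L), "empty")
  low <- make_align("r", "chr1", 0L, aln_len = 500L, mapq = 10L)
  expect_equal(coverage_fraction(low, "chr1", 0L, 1000L), 0.0)
  # agreement with position-counting oracle on random sets
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    s <- sample(0:900, n, replace = TRUE)
    al <- do.call(bind_aligns, lapply(seq_len(n), function(k)
      make_align(paste0("r", k), "chr1", s[k],
                 aln_len = sample(30:200, 1))))
    expect_equal(coverage_fraction(al, "chr1", 100L, 800L),
                 coverage_oracle(al, "chr1", 100L, 800L))
  }
})

test_that("repeat calling selects by score ratio, edit distance and support", {
  mk_multi <- function(n, alt_nm = 1L, nm = 0L, contig = "chr1") {
    do.call(bind_aligns, lapply(seq_len(n), function(i)
      make_align(paste0("m", i), contig, 1000L + i * 10L, mapq = 3L, nm = nm,
                 xa = sprintf("%s,%d,+,%d", contig, 5000L + i * 10L, alt_nm))))
  }
  # best 60, second-best 40 via aln_len 60, alt_nm 5, score_k 4: 40/60 < 0.8
  bad_ratio <- do.call(bind_aligns, lapply(1:25, function(i)
    make_align(paste0("b", i), "chr1", 1000L + i, aln_len = 60L, mapq = 3L,
               xa = sprintf("chr1,%d,+,5", 5000L + i))))
  expect_equal(nrow(call_repeat_circles(bad_ratio, "s", max_edit = 10L, min_coverage = 0)), 0L)

  # edit distance 3 on the alternative -> excluded under "< 3"
  high_edit <- mk_multi(25L, alt_nm = 3L)
  expect_equal(nrow(call_repeat_circles(high_edit, "s", min_coverage = 0)), 0L)

  # 19 qualifying reads -> below the support cut; 20 -> called
  expect_equal(nrow(call_repeat_circles(mk_multi(19L), "s", min_coverage = 0)), 0L)
  calls <- call_repeat_circles(mk_multi(20L), "s", min_coverage = 0)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$mode, "repeat")
  # spans leftmost primary to rightmost alternative position
  expect_equal(calls$start, 1010L)
  expect_equal(calls$end, 5200L + 100L)

  # reads without alternative hits are skipped, counted in the attribute
  mixed <- bind_aligns(mk_multi(20L), make_align("plain", "chr1", 100L))
  out <- call_repeat_circles(mixed, "s", min_coverage = 0)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("repeat detector recovers planted tandem-array circles", {
  w <- small_world()
  al <- w$alignments[["P1_young"]]
  calls <- call_repeat_circles(al, "P1_young")
  rd <- w$cohort$circles[w$cohort$circles$rdna, ]
  hit <- calls[calls$contig == rd$contig, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$start - rd$start), 100L)
  expect_lte(abs(hit$end - rd$end), 100L)
  expect_gte(hit$support, 20L)
})

test_that("saturation subsampling is nested, deterministic and monotone", {
  w <- small_world()
  det <- function(a) call_unique_circles(extract_junction_evidence(a), a, "s")
  for (s in w$cohort$sheet$sample) {
    al <- w$alignments[[s]]
    sat <- saturation_curve(al, det, fractions = seq(0.05, 1, 0.05), seed = 2)
    expect_equal(sat$n_circles[nrow(sat)], nrow(det(al)))
    expect_true(all(diff(sat$n_circles) >= 0), info = s)
    expect_true(all(diff(sat$n_reads) >= 0), info = s)
  }
  al <- w$alignments[["P1_young"]]
  s1 <- saturation_curve(al, det, fractions = c(0.3, 0.6, 1), seed = 2)
  s2 <- saturation_curve(al, det, fractions = c(0.3, 0.6, 1), seed = 2)
  expect_identical(s1, s2)
  expect_error(saturation_curve(al, det, fractions = c(0, 0.5)), "fractions")
  expect_error(saturation_curve(al, det, fractions = c(0.5, 1.2)), "fractions")
})
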