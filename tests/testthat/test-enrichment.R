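test_that("feature annotation uses any-overlap on half-open intervals", {
  g <- data.frame(group_id = "c1", contig = "chr1", start = 1000L,
                  end = 2000L, stringsAsFactors = FALSE)
  inside <- data.frame(kind = "origin", contig = "chr1", start = 1500L,
                       end = 1600L, name = "ARS1")
  expect_true(annotate_features(g, inside)[1, "origin"])
  abutting <- data.frame(kind = "origin", contig = "chr1", start = 2000L,
                         end = 2100L, name = "ARS2")
  expect_false(annotate_features(g, abutting)[1, "origin"])
  one_base <- data.frame(kind = "centromere", contig = "chr1", start = 1999L,
                         end = 2100L, name = "CEN")
  expect_true(annotate_features(g, one_base)[1, "centromere"])
  bad <- data.frame(kind = "enhancer", contig = "chr1", start = 1L,
                    end = 2L, name = "x")
  expect_error(annotate_features(g, bad), "unknown feature kind")
})

test_that("planted centromere-spanning circles are flagged", {
  res <- full_run()
  feats <- res$genome$features
  cen <- feats[feats$kind == "centromere", ]
  spanning <- res$groups$contig == cen$contig &
    res$groups$start < cen$end & res$groups$end > cen$start
  if (any(spanning)) {
    pres <- annotate_features(res$groups, feats)
    expect_true(all(pres[spanning, "centromere"]))
  }
  # and non-spanning circles are not
  pres <- annotate_features(res$groups, feats)
  expect_true(all(!pres[!spanning, "centromere"]))
})

test_that("motif scanning is exact, stranded and junction-aware", {
  s <- paste0("AAAAAAA", "ACGCGT", "TTTTTTT")
  expect_true(scan_motif(s, "ACGCGT"))
  expect_false(scan_motif(s, "GGGGGG"))
  # reverse complement of ACGCGT is ACGCGT (palindromic); use asymmetric motif
  expect_true(scan_motif("AAACCCTTTAAA", "AGGGTT"))        # minus strand
  expect_false(scan_motif("AAACCCTTTAAA", "AGGGTT", both_strands = FALSE))
  # motif spanning the circular junction only
  circ <- paste0("GTAAAAAAAAAC", "")   # wrap gives ...ACGT...
  expect_true(scan_motif("GTAAAAAAAAAC", "ACGT", wrap = TRUE))
  expect_false(scan_motif("GTAAAAAAAAAC", "ACGT", wrap = FALSE))
  expect_error(scan_motif(s, ""), "empty motif")
  expect_error(scan_motif(s, "ACGN"), "A/C/G/T")
})

test_that("two-sided Fisher matches the enumeration oracle everywhere", {
  # exhaustive over all tables with small totals
  for (n in 2:12) {
    parts <- t(utils::combn(n + 3, 3))
    for (r in seq_len(nrow(parts))) {
      cuts <- parts[r, ]
      cell <- c(cuts[1] - 1, cuts[2] - cuts[1] - 1, cuts[3] - cuts[2] - 1,
                n + 4 - cuts[3] - 1)
      ft <- fisher_two_sided(cell[1], cell[2], cell[3], cell[4])
      expect_equal(ft$p, fisher_enum_p(cell[1], cell[2], cell[3], cell[4]),
                   tolerance = 1e-10)
    }
  }
  # random larger tables up to total 200
  set.seed(5)
  for (i in 1:300) {
    n <- sample(20:200, 1)
    cell <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    ft <- fisher_two_sided(cell[1], cell[2], cell[3], cell[4])
    expect_equal(ft$p, fisher_enum_p(cell[1], cell[2], cell[3], cell[4]),
                 tolerance = 1e-9)
  }
})

test_that("Fisher conventions: balance, symmetry, zero margins, odds ratio", {
  expect_equal(fisher_two_sided(5, 5, 5, 5)$p, 1)
  t1 <- fisher_two_sided(8, 3, 44, 152)
  t2 <- fisher_two_sided(8, 44, 3, 152)   # transpose
  expect_equal(t1$p, t2$p)
  expect_equal(fisher_two_sided(0, 0, 10, 20)$p, 1)
  expect_equal(fisher_two_sided(2, 3, 4, 6)$odds_ratio, (2 * 6) / (3 * 4))
  expect_error(fisher_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("BH adjustment is a step-up within each family", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.004, 0.1, 0.9, 0.5, 0.03, 0.2)
  adj <- bh_adjust(p)
  expect_equal(adj[which.min(p)], min(1, 6 * min(p)))
  expect_true(all(adj <= 1) && all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Wilcoxon test is exact for small untied samples", {
  # complete separation, 4 vs 4: exactly 2 of the 70 assignments as extreme
  p <- wilcoxon_two_sided(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(p, 2 / 70)
  expect_equal(wilcoxon_two_sided(c(1, 2), c(1, 2)), 1)
  x <- c(1.2, 3.4, 0.5); y <- c(2.2, 8.1, 0.9, 4.4)
  expect_equal(wilcoxon_two_sided(x, y), wilcoxon_two_sided(y, x))
  expect_error(wilcoxon_two_sided(numeric(0), 1:3), "empty")
})

test_that("exact Wilcoxon agrees with permutation enumeration to n=6 per arm", {
  set.seed(9)
  for (nx in 1:6) for (ny in 1:6) {
    vals <- sample(seq(0, 1, length.out = 50), nx + ny)  # no ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(wilcoxon_two_sided(x, y), wilcox_enum_p(x, y),
                 tolerance = 1e-12,
                 info = paste("nx =", nx, "ny =", ny))
  }
})

test_that("the enrichment screen builds tables per feature and family", {
  set.seed(2)
  classes <- c(rep("I", 3), rep("II", 3), rep("III", 4), rep("IV", 10))
  n <- length(classes)
  pres <- cbind(origin = c(rep(TRUE, 6), rep(FALSE, 14)),
                intron = rep(FALSE, n),
                LTR = sample(c(TRUE, FALSE), n, replace = TRUE))
  rownames(pres) <- paste0("g", seq_len(n))
  motifs <- cbind(M1 = sample(c(TRUE, FALSE), n, replace = TRUE))
  rownames(motifs) <- rownames(pres)
  out <- enrichment_screen(classes, pres, motifs,
                           lengths = seq_len(n) * 100)
  r <- out$results
  # perfect origin separation: smallest possible p for these margins
  orig <- r[r$feature == "origin", ]
  expect_equal(orig$p, fisher_enum_p(6, 0, 0, 14), tolerance = 1e-12)
  # absent feature -> zero margin -> p = 1
  expect_equal(r$p[r$feature == "intron"], 1)
  # families adjusted independently
  gf <- r[r$family == "genomic_feature", ]
  ce <- r[r$family == "cis_element", ]
  expect_equal(gf$adjusted_p, bh_adjust(gf$p))
  expect_equal(ce$adjusted_p, bh_adjust(ce$p))
  # row order does not matter
  perm <- sample(n)
  out2 <- enrichment_screen(classes[perm], pres[perm, ], motifs[perm, ,
                                                                drop = FALSE],
                            lengths = (seq_len(n) * 100)[perm])
  expect_equal(out$results$p, out2$results$p)
  expect_equal(out$size_test, out2$size_test)
  expect_error(enrichment_screen(rep("I", 4), pres[1:4, ]), "class group")
  expect_error(enrichment_screen(c("I", "V"), pres[1:2, ]), "classes must")
})
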