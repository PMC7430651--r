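---
title: "Circular DNA detection, inheritance and quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular DNA detection, inheritance and quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and procedures: what
each stage assumes, which parameters matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design
choices were settled.

## Evidence model for circular DNA

A circle excised from locus `[s, e)` leaves three read-level signatures in
a coordinate-sorted alignment file of rolling-circle-amplified DNA:

1. **Junction reads.** A read crossing the junction aligns partially at one
   boundary with its remainder soft-clipped; the clipped segment maps at
   the other boundary. The implied interval runs from the leftmost to the
   rightmost coordinate among the aligned and clipped segments — exactly
   `[s, e)` for an ideal read.
2. **Outward discordant pairs.** A fragment crossing the junction yields a
   pair whose leftmost mate points left (minus strand) and rightmost mate
   points right — impossible on the linear reference, diagnostic of a
   circle. The implied interval spans the pair and is contained in the
   circle.
3. **Coverage.** Reads sampled from a circle tile `[s, e)`; a genuine
   circle call should have near-complete coverage.

Unique-region detection clusters evidence items (sorted by genomic
position) into candidates: an item joins the first open cluster whose
consensus interval (member-wise min start / max end) it reciprocally
overlaps by the merge fraction, otherwise it opens a new cluster — ties are
broken by genomic order, which keeps the procedure deterministic and
input-order-free. Candidates are then iteratively merged while any two
overlap each other by ≥ 50% of *each* interval's own length, support is
the number of distinct evidence read ids, and calls survive with support
≥ 5 (the literal reading of "more than 4") and coverage strictly > 0.90.
All three evidence kinds count toward support; coverage counts reads with
mapping quality ≥ 20, mirroring the quantification stage's policy for
unambiguous alignment.

## Repeat-region detection

Tandem arrays (rDNA) and dispersed repeat families (Y') defeat the
junction model: a circle junction inside a tandem array reproduces the
array's own sequence, so no reads are soft-clipped there, and mapping
qualities collapse to ~0. The repeat detector instead exploits the
multi-mapping structure itself:

* A read qualifies when its best and counted alternative alignments both
  have edit distance ≤ 2 and the second-best score is at least 80% of the
  best. Aligner tags provide positions and edit distances but not paired
  scores, so score is the proxy `aligned_length − 4·NM` (the factor 4
  matches the conventional mismatch-penalty-to-match-bonus ratio; the
  ratio threshold, not the absolute score, is what matters).
* The read's candidate interval spans the leftmost to rightmost position
  among the primary and the *tied* second-best alternatives. With exact
  repeat copies the second-best tier is a score tie; restricting to a
  single arbitrary member of the tie would make the interval an accident of
  tag order, so the span covers all of them (same-contig hits only).
* Candidates cluster as above at 80% reciprocal overlap, clusters need
  ≥ 20 reads ("support lower than 20 removed"), merged calls need coverage
  ≥ 0.80 by the selected reads (no mapping-quality filter — these reads
  are multireads by construction).

A consequence worth stating: a repeat circle is resolvable only when the
candidate spans are a large fraction of the circle. For a circle spanning
*k* copies of unit length *u*, the span is ≈ (k−1)·u + read length, so
recovery at 80% reciprocal overlap needs k ≥ 5. The default cohort plants
its rDNA-like and Y'-like circles across ≥ 5 copies; single-copy repeat
circles are genuinely ambiguous for this algorithm (on real data they
surface as locus-level calls), and the 19-read control circle documents
the support boundary instead.

## Inheritance classification

Calls are matched across samples on the same contig when both start and
end coordinates agree within ±300 bp (unique) or ±400 bp (repeat; a mixed
pair uses 400 bp, the permissive choice). Cross-sample grouping is
single-linkage over pairwise matches with the canonical interval as the
member-wise median of starts and ends — single linkage plus a median
canonical interval makes grouping independent of sample order.

Within a population, presence over (young, progeny, aged) maps to classes
I–V; "present in young" means present in at least one young sample of that
population, and class V requires absence from *all* young samples of every
population. Conflicting per-population classes resolve to the highest
order of representation, I > {II, III, IV} > V; two classes of the same
order make the group ambiguous, which all downstream statistics exclude.

The class IV rescue re-runs both detectors on the aged samples with
support and coverage thresholds disabled (support ≥ 1, coverage ≥ 0) and
re-intersects class IV groups under the standard tolerances; the reported
fraction is the share with no matching aged call at all. The de novo rate
divides the number of class V circles seen in a population's aged
subpopulation by recovered cells × ~15 divisions; with no class IV groups
the rescue fraction is reported as not applicable rather than 0 or 1.

## Quantification

Counting uses any-overlap of the aligned segment with the canonical
interval at mapping quality ≥ 20; tandem-array groups are counted with no
quality filter because their reads cannot be unambiguous. Size factors are
the median of ratios: reference rows are rows positive in every sample,
each row is divided by its geometric mean, and a sample's factor is the
median of its ratios. With an even number of reference rows the median is
the arithmetic midpoint of the central pair (DESeq2 interpolates on the
log scale; the package's unit tests pin the exact agreement on odd counts
and document the difference). If no reference row exists the function
stops — a pseudo-reference fallback would silently change the estimator.
Scaling one sample by *c* multiplies its size factor by *c* relative to
every other sample and leaves normalized counts unchanged up to one global
constant; the tests assert that exact form.

Zeros are real in this data (class IV circles have no aged reads), so the
log10 view and fold changes add a pseudocount of 1, anchoring zero at 0
and leaving order statistics intact. The recurrence filter keeps rows with
nonzero raw counts in ≥ 2 samples — detection here means reads over
already-called coordinates, not an independent per-sample call. PCA runs
on samples as observations with centering and unit scaling (a
zero-variance circle is an error naming the row); hierarchical clustering
uses Manhattan distance with average linkage for both rows and columns,
and dendrograms export as Newick.

Spike-in normalization divides the reads on the rDNA locus, the Y' loci
and the other called circles by the summed reads on the four spike-in
plasmid contigs (pUC19_yEGFP, pSH63, p4339, pRS316; the set is
configurable). Because every plasmid is present at fixed abundance, these
ratios are invariant to sequencing depth and track true per-cell
abundance even when one species dominates the library — which is exactly
what happens in aged samples, where the median-of-ratios view (driven by
the all-positive reference rows, i.e. the rDNA group itself) normalizes
the rDNA signal flat while the spike-in ratio exposes the planted
400-fold accumulation.

## Enrichment statistics

A feature is present on a circle if its interval overlaps the canonical
interval by ≥ 1 base (half-open arithmetic: an abutting feature does not
overlap); replication origins deliberately use the same any-overlap rule
because origin annotations are low-resolution. Motifs are exact A/C/G/T
substring matches scanned on both strands, with the subject sequence
extended by motif length − 1 bases wrapping end→start: the molecule is
circular and a motif spanning the junction is a genuine occurrence
(`wrap = FALSE` restores a linear scan).

The class I+II versus class III+IV contrast uses the two-sided Fisher
exact test with the R convention (sum over margin-fixed tables with point
probability ≤ observed), the sample odds ratio (a·d)/(b·c), and p = 1 for
zero-margin tables. Genomic features and cis elements are BH-adjusted as
separate families. The Wilcoxon test is exact by enumeration when the
combined sample size is ≤ 12 without ties — which covers every group-size
comparison this design produces — and falls back to the tie-corrected
normal approximation otherwise.

## The synthetic cohort: what it emulates

The default study conditions (`default_cohort_design()`):

* 2 populations × (young, progeny, aged), one library each, 30,000
  primary records per library, read length 100, sequencing error injected
  only as edit-distance noise (rate 0.001/base).
* 64 young-present circle species of which 60 are class IV (93.75%, the
  dominant young-circle-loss regime), one class III circle, two de novo
  class V circles (one aged-only, one progeny-only), one circle planted
  with conflicting per-population patterns (I in P1, IV in P2 — resolves
  to I) and one same-order conflict (II vs III — ambiguous).
* An rDNA-like circle spanning tandem units 5–9 (class I) with abundance
  inflated 400× in aged samples, and a Y'-like circle spanning six
  dispersed copies (class II) inflated 600×.
* Three detection controls pinned to the thresholds: a unique circle with
  exactly 4 junction reads, a unique circle covered over only half its
  span, and a tandem circle with 19 multi-mapping reads.
* Two class IV circles carry 3 sub-threshold junction reads in aged
  samples, so the unfiltered rescue has something to rescue (58/60 = 96.7%
  with zero evidence).
* Four spike-in plasmids at fixed abundance, plus low-level linear
  background reads.

Read depths follow a library model: each library's records are split
across the molecules present in that sample in proportion to relative
abundance, so rDNA amplification in aged samples compresses every other
category — including the plasmids, which is why spike-in ratios recover
abundance ratios exactly. One deliberate departure from pure
proportionality: a truly present planted circle receives at least 35
records (`depth_floor`). Real libraries run tens of millions of reads, so
a present circle always clears the detection cut even in a 99%-rDNA aged
library; the floor reproduces that detectability structure at toy scale
without simulating the full read count. Plasmid, background and
repeat-circle depths stay strictly proportional.

The generator is tag-level, not base-level: no sequences or quality
strings are emitted, error appears only as NM values, junction reads
always know where their clipped segment maps, repeat reads list their
homologous copies as alternative hits placed inside the circle, and
internal reads tile their span evenly (deterministic coverage). Passing
tests therefore demonstrate the *algorithms* — threshold boundaries,
merging, classification, normalization, statistics — under clean evidence;
they do not demonstrate robustness to alignment artifacts, chimeric
amplification, uneven coverage, or mismapped clips, all of which real
Circle-Seq data contains. Boundary accuracy on real repeat regions is
locus-scale, not read-scale.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at SAM/GFF boundaries (1-based).
* Subsampling for the saturation analysis hashes read ids to [0, 1) with a
  polynomial string hash mixed with the seed (all arithmetic exact in
  doubles below 2^53) and keeps ids below the fraction — subsamples are
  nested by construction, so the discovery curve is monotone under the
  detectors' monotone thresholds, and the result is independent of record
  order.
* Threshold semantics are literal: "> 4 reads" keeps support ≥ 5;
  "> 90%" coverage is strict; "lower than 20 removed" keeps ≥ 20;
  "< 80% removed" keeps ≥ 0.80; "≥ 80%" score ratio is inclusive;
  "edit distance < 3" keeps ≤ 2.
* The score-ratio direction is second-best/best ≥ 0.8 — a best/second-best
  ratio is ≥ 1 by definition and would select every read.
* Empty inputs: empty evidence yields empty call tables (exit normally);
  an empty class IV set makes the rescue fraction NA; a zero plasmid count
  is an error (the ratio is undefined); a group with zero members is an
  error.
* `run_pipeline()` validates every threshold before any stage runs, stamps
  each run with a manifest (config snapshot, seed, per-stage record counts
  and wall times), and derives all stage randomness from the single
  top-level seed by fixed offsets, so each stage can be re-run
  independently and a run is reproducible bit for bit.

Problem sizes throughout (6 samples × 30k records, ~70 circles, 20-point
saturation grids, 1000-trial property checks) were chosen so the full
analysis and its test suite execute in a few minutes on one CPU while
still exercising every threshold boundary from both sides.

## Known limitations

* The repeat detector cannot resolve single-copy repeat circles (see
  above); dispersed-repeat circles are modeled as multi-copy clusters.
* The probabilistic realignment of clipped segments is out of scope; the
  detector trusts the mapped clip positions carried in tags.
* Motif scanning is exact-match only (no PWMs, no IUPAC degeneracy), on
  the reference sequence of the canonical interval — variants on the
  circle are not incorporated.
* The cis-element motif list shipped with the package is a synthetic
  stand-in for a curated binding-site collection; on the random toy
  genome its hits are baseline occurrences.
* The de novo rate uses the planted recovered-cell count; on real data
  that number comes from cell counting and its uncertainty dominates.
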