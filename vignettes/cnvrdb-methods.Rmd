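---
title: "CNVR construction from multi-sample read depth: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNVR construction from multi-sample read depth: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrdb)
```

## The problem

Copy number variants (CNVs) are unbalanced structural variants: genomic
segments whose diploid copy number differs from the reference value of 2.
In multi-sample whole-genome sequencing studies they are detected from
read depth — a window of the genome covered by half the expected reads in
one sample suggests a heterozygous deletion (CN1), twice the expected
reads a duplication (CN4), and so on. Population-scale reporting then
groups per-sample CNVs that substantially overlap into CNV regions
(CNVRs), the unit carried forward to genotype tables, population-genetic
checks, annotation, and browsable reports.

`cnvrdb` implements this downstream pipeline for cohorts of hundreds of
samples (its design target is multi-breed cattle WGS panels, but nothing
is cattle-specific): calling, sample quality control, CNVR construction,
genotype assignment, Hardy-Weinberg and parity testing, clustering,
annotation, and a self-contained interactive HTML database. A synthetic
cohort generator with known truth makes every stage testable without any
sequence data.

## Coordinate conventions

All coordinates are 1-based inclusive; the length of an interval is
`end - start + 1`. The genome is tiled into non-overlapping windows of
`window_length` bp (default 1,000), so window *i* of a chromosome is
`[(i-1)*WL + 1, i*WL]`. A trailing window shorter than WL is kept in the
layout but excluded from calling, which avoids length artifacts at
chromosome ends. Converters to 0-based half-open (BED) conventions exist
only at I/O boundaries.

## The read-depth caller

The caller is deliberately simple — a stand-in with the same external
contract as multi-sample mixture-model callers (integer genotypes CN0-CN8
with CN2 reference, 1-kb windows, normalization before calling, calls
only when three adjacent windows deviate). The full mixture-of-Poissons
machinery of such callers is intentionally *not* reimplemented here; the
pipeline is caller-agnostic and also accepts externally produced CNV call
tables.

1. **Normalization** (`normalize_counts`): each sample is scaled so its
   genome-wide total equals the cohort mean total. Zero-total samples are
   excluded with a warning.
2. **Per-window estimates** (`estimate_window_cn`): the reference rate
   `lambda_w` is the across-sample *median* of normalized counts in the
   window — robust to a minority of carriers. The copy-number estimate is
   `round(2 x / lambda_w)` clipped to [0, 8]; the window is flagged
   significant iff the estimate differs from 2 *and* the exact two-sided
   Poisson tail probability of `x` under `lambda_w`
   (`2 min(P(X <= x), P(X >= x))`) is below `alpha` (default `1e-3`).
   Windows with `lambda_w = 0` are masked. **Known limitation:** loci
   where more than half the cohort carries a variant mis-reference,
   because the median then tracks the carrier rate; common variants can
   therefore produce mirror-image calls in non-carriers.
3. **Segmentation** (`segment_calls`): per sample and chromosome, maximal
   runs of at least `min_adjacent_windows` (default 3) *consecutive*
   flagged windows of consistent direction (all estimates below 2, or all
   above) become one call, so the smallest reportable CNV is 3 kb and all
   call lengths are multiples of WL. A flagged gain window terminates a
   loss run and vice versa (mixed adjacent events yield abutting calls).
   The call genotype is the median of the member window estimates, with
   half-values rounded toward CN2 — a deterministic choice where the
   window evidence is balanced.

At `alpha = 1e-3` and a diploid rate of 100 reads/window, the per-window
flag threshold is roughly `x <= 68` or `x >= 135`. Heterozygous
duplications (expected rate 150) therefore flag each window with
probability only ~0.90; long CN3 events often split on interior
unflagged windows. This is an analytic property of the per-window
contract, quantified in the acceptance suite, and the main reason CN3
boundary recovery lags the other classes.

## Sample quality control

QC is strictly dataset-wise: sequencing batches differ in platform, read
length and coverage, and read-depth comparison across batches produces
spurious genotype skew. Combining batches into one calling group is
refused unless explicitly overridden.

* **PCA outliers** (`pca_outliers`): samples are projected on the first
  two principal components of the column-centered normalized count
  matrix; a sample is flagged when its Euclidean distance from the
  coordinate-wise median exceeds `k_mad` (default 6) times the median
  absolute deviation (scaled, `stats::mad`) of those distances. This is a
  deterministic replacement for by-eye outlier calls. With few samples
  the top components align with the most extreme noise profile, so the
  rule retains a per-sample false-flag rate of roughly 0.3-1% on clean
  cohorts — the acceptance suite measures this honestly rather than
  hiding it.
* **Tukey fences** (`iqr_outliers`): per dataset, a sample is problematic
  when its deletion proportion (fraction of its calls with CN < 2 — a
  call-count fraction, not a base-pair fraction) or its total call count
  lies more than 1.5 IQR beyond the quartiles (type-7 quantiles). An
  optional high-coverage fence on the metadata coverage field is off by
  default.

All calls from failing samples are removed (`apply_qc`, idempotent).

## CNVR construction and genotypes

* **Clustering** (`cluster_cnvs`): two calls satisfy the reciprocal
  overlap criterion when the shared length is at least 50% of *both*
  calls. CNVRs are the connected components of this pairwise graph
  (single linkage). Single linkage is the common practice in the
  predecessor pipelines and keeps membership independent of input order;
  the threshold is exposed (`ro`). Merging is genotype-agnostic, so DEL
  and AMP calls may share a CNVR; categories are DEL (all member CN < 2),
  AMP (all > 2), MIX (both).
* **Singleton filter** (`filter_singletons`): CNVRs observed in fewer
  than 2 *distinct* samples are dropped.
* **Genotype assignment** (`assign_genotypes`): per sample, member calls
  are grouped by CN class and the class with the largest aggregate width
  wins; ties go to the class closest to CN2; a residual tie (CN1 vs CN3)
  resolves to the lower copy number — the paper-silent case needs a
  deterministic rule, and deletions are the more common and more reliably
  detected class in short-read data. Non-carriers get a provisional CN2.
* **CN2 correction** (`cn2_correction`): because 50% reciprocal overlap
  permits overlapping CNVRs, a sample's provisional CN2 at one CNVR is
  downgraded to CN_ (undetermined, encoded `NA`) when that sample carries
  a CNV in any other CNVR overlapping it by at least 1 bp. The corrected
  matrix feeds every downstream summary.
* **Cross-dataset merging** (`merge_cnvr_sets`): union mode coalesces
  overlapping or bookended regions into a non-redundant genome span;
  unique-coordinates mode counts CNVRs with identical coordinates across
  datasets once.

## Population-genetic checks

* **Hardy-Weinberg** (`hwe_test`): only diallelic autosomal spectra are
  testable — observed classes within {CN0, CN1, CN2} (deletion allele) or
  {CN2, CN3, CN4} (duplication allele), at least two classes present
  (qualification requires two, not all three; the class spectrum is
  reported). The minor-allele frequency is estimated from the counts and
  a Pearson goodness-of-fit statistic with 1 df compares observed counts
  with `n(q^2, 2pq, p^2)`; a CNVR is "in HWE" when P >= 1e-5. No
  continuity correction by default (a Yates-style option exists); CN_
  samples are excluded from the denominators.
* **Parity** (`parity_test`): even-CN classes (homozygote-like; CN6 is
  treated as even although enumerations sometimes omit it — the test is
  defined by homozygote vs heterozygote frequencies) must not be
  outnumbered by odd-CN classes; ties pass. Under Hardy-Weinberg
  proportions `p^2 + q^2 >= 2pq` for every q, but at finite n the
  sampling noise flips the comparison with non-trivial probability when
  q approaches 0.5: at q = 0.4, n = 100 the pass probability is only
  ~0.69, and averaged over q uniform on (0, 0.4] it is ~0.956. A >= 99%
  pass-rate expectation for that world is therefore not attainable; the
  acceptance suite states the world plainly and reports the measured
  rate.
* **Clustering** (`cluster_samples`): distance is 1 minus the Spearman
  rank correlation of genotype vectors (average ranks for the pervasive
  integer ties; CN_ pairwise-excluded), agglomeration is ward.D2.
  Degenerate pairs (no shared genotyped CNVRs, or a zero-variance
  vector) get the maximum distance 2 with a warning.

## Annotation

Genes come from GFF3 with parent-child relations resolved; introns are
derived from the gaps between consecutive exons of each transcript
rather than trusting annotation-supplied introns. A CNVR is associated
with a gene when it overlaps the gene body extended by `gene_flank` on
both sides; the 5-Mb default mirrors the upstream study's printed value
but is deliberately configurable — it is unusually large for gene
association and may well have been intended as 5 kb. Body hits are
classified per sub-feature (CDS/UTR/exon/intron); flank-only hits are
upstream/downstream by strand. Overlap labels are
`"<component> <category>"` in lower case ("cds del"), the searchable
key of the database. QTL/gap/repeat/segmental-duplication tracks use the
>= 1 bp rule, with a `boundary_in_gap` caveat flag when a CNVR boundary
falls inside an assembly gap.

## The HTML database

`build_database` writes a static tree openable from disk: an index page
(filter panel with defaults 1 kb-3 Mb length and 2 samples; statistics
before/after filtering; searchable CNVR, gene, QTL and sample tables
with CSV export; client-side favorites/comments with export to a text
file) and one detail page per CNVR (summary, genotype and breed bar
plots, overlaps, HWE/parity results, sample list, an external
genome-browser URL, and seeded per-genotype read-depth plots). Plots are
hand-written SVG, so the output is text-only and byte-stable; read-depth
traces replace read-alignment screenshots because the pipeline's input
is the count matrix, preserving the purpose (visual verification of
depth support at the CNVR with up to 3 randomly chosen samples per
genotype). `filter_stats()` is the R-side arithmetic of the Statistics
panel, used by the tests; the browser JavaScript recomputes the same
numbers.

## The synthetic cohort generator

`simulate_cohort` draws, per breed and locus, diploid genotypes under
Hardy-Weinberg proportions (variant alleles ~ Binomial(2, q)); deletion
loci give CN `2 - alleles`, duplication loci CN `2 + gain * alleles`
capped at 8. A per-allele gain of 1 yields CN3/CN4; a multi-copy allele
(gain 3) emulates high-amplification loci where heterozygotes are CN5
and homozygotes CN8. `simulate_counts` gives window counts
`Poisson(lambda * CN/2 * coverage-scale * batch-scale)` with
`lambda = 100` reads per diploid window by default (the usual target
when the window length is chosen); noise can be switched to negative
binomial (overdispersion) or off entirely — the noise-free mode is the
analytic oracle used by the caller contract tests. Poisson (rather than
negative binomial) is the default because it matches the depth-model
family of the caller and keeps the test oracles closed-form.
`plant_problem_samples` corrupts chosen samples: binomial thinning to a
fraction of cohort depth (low coverage; default multiplier 0.3,
a <5x sample in a ~10x cohort), or a bias factor applied to a random
window subset (batch artifact).

What the generator does *not* emulate: GC and mappability bias,
segmental-duplication depth artifacts, read-level errors, linkage
between loci, or sex chromosomes. A green test therefore establishes the
correctness of the downstream logic under the stated depth model, not
caller performance on real sequencing data.

## Acceptance experiments: the stated worlds

The acceptance suite (`tests/testthat/test-acceptance.R`) fixes one
world per criterion; `scripts/acceptance.R` recomputes the headline
caller-contract target. Choices made once and not revisited:

* *Caller floor* — 20 samples, 2-Mb chromosome, noise-free counts, one
  sample carrying CN1 deletions of 1-6 kb at loci >= 20 windows apart.
  The minimum emitted call length is exactly 3,000 bp.
* *Poisson recovery* — 20 samples x 5 Mb, 160 planted single-carrier
  events, lengths cycling {5, 6, 8, 10} kb (read-depth CNV length
  distributions skew short), CN classes {0, 1, 3, 4} balanced. An event
  is recovered when the union of the sample's overlapping calls has both
  boundaries within one window and all its calls carry the true
  genotype (union matching is the standard breakpoint-benchmark
  protocol; a single-call requirement would double-count run splits).
* *HWE type-I* — 2,000 multinomial tables at q = 0.3, n = 500.
* *Parity* — 10,000 tables, q uniform on (0, 0.4], n = 100 (see the
  parity discussion above for why the 99% expectation fails).
* *Breed clustering* — two breeds of 8 samples, 15 disjoint
  breed-specific loci each at q = 0.5, truth genotypes clustered and cut
  at k = 2; purity against truth over 50 replicates.
* *QC* — 30 samples x 2,000 windows (the upstream study's smallest
  dataset had ~32 samples); recall on planted low-coverage and
  batch-outlier samples, specificity on clean Poisson cohorts. The
  specificity expectation (95% of replicates with zero flags) exceeds
  what the PCA-MAD rule delivers (~0.92); the measured value is
  reported, not adjusted.
* *Database* — ~200 generated CNVRs over 30 samples; every internal link
  must resolve, filter statistics must equal direct recomputation, and
  per-genotype plot sampling must be seed-deterministic and capped at 3.

## Numerical and degenerate-input choices

* Copy-number rounding uses base R `round` (half-to-even) for window
  estimates; run genotypes round half-values toward CN2 by rule.
* Poisson tails are exact (`ppois`), with non-integer normalized counts
  handled by `floor`/`ceiling` on the respective tails.
* Quantiles are type 7 (linear interpolation) everywhere.
* Constant QC inputs have IQR 0 and flag nothing; `k_mad = Inf` disables
  the PCA rule; an all-identical cohort yields no PCA outliers.
* Monomorphic or multi-allelic genotype spectra disqualify from the HWE
  test with a stated reason; zero genotyped samples make the parity test
  `NA`.
* Empty call sets propagate as empty CNVR sets; the database renders a
  zero-state index.

## Limitations

The caller is a contract-compatible stand-in, not a mixture model: its
per-window test is marginal (no information pooling across windows or
samples), so sensitivity for heterozygous duplications is materially
below that for deletions, and loci with carrier frequency above 50%
mis-reference. Breakpoints are window-resolution by construction. The
HWE test covers diallelic spectra only. Sex chromosomes are treated with
autosome semantics throughout.
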