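---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters
and why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and the numerical decisions taken
where the design was genuinely open.

# The study design the package serves

The package analyses two-group comparisons of growing mouse oocytes —
typically an oocyte-specific conditional knockout of the H3K9
methyltransferases EHMT1/EHMT2 (single or double) against littermate
controls — across four data layers: ultra-low-input native ChIP-seq for
the broad euchromatic mark H3K9me2, whole-genome bisulfite sequencing,
low-input RNA-seq, and TMT isobaric-label proteomics. Every layer is a
tabular two-group problem, which is why all user-facing functions take
and return tibbles and chain with the pipe.

# Windowed ChIP and broad-domain calling

H3K9me2 in oocytes forms megabase-scale, low-amplitude domains rather
than punctate peaks, so the caller works on fixed 10-kb windows rather
than peak models.

* **Windows.** Consecutive non-overlapping 10-kb tiles per chromosome.
  A terminal partial tile is kept when it is at least half the window
  width; at full mouse-genome scale this reproduces the canonical
  272,566-window count. The half-width rule is a package decision
  (`tile_windows()` is configurable) — a sub-half tile has too little
  support for a stable RPKM.
* **Quantification.** RPKM = count / ((width/1000)·(library/10⁶)).
  log₂RPKM uses a pseudocount of 2⁻⁴ = 0.0625 RPKM: small enough that a
  zero-count window sits at log₂RPKM = −4, far below any plausible
  enrichment threshold, large enough to keep the transform finite.
* **Artifact mask.** Windows whose input (chromatin without IP) signal
  is implausibly high are collapsed-repeat artifacts. The rule is: mean
  RPKM per replicate *set* of input libraries strictly above a
  threshold in at least one set. 6 RPKM is the full-genome default; it
  corresponds to roughly 16× the uniform input background on a 2.7-Gb
  genome (≈ 0.37 RPKM at any depth, since depth cancels in RPKM). On a
  desk-scale synthetic genome the uniform background itself is
  10⁹/genome-bp RPKM (≈ 67 at 15 Mb), so an absolute 6 would mask
  everything; `rpkm_threshold = NULL` therefore switches to 3× the
  median input RPKM, which separates a 10× artifact inflation from
  background at any scale. The per-set-mean reading of the rule (rather
  than per-library) is a documented choice; both behaviours are
  reachable through `sample_sets`.
* **Enrichment threshold.** log₂RPKM > 2.5 (strict) is the published
  operating point for mature (d25) GV-oocyte H3K9me2 at ~57 M reads on
  the mouse genome. The threshold is a property of that depth and
  genome: on the default synthetic genome (3 × 5 Mb, 10⁶ reads) the
  background sits near log₂RPKM ≈ 5.5, so the synthetic analyses call
  enrichment at the data-driven midpoint `median(log₂RPKM) +
  log₂(fold)/2`, halfway between background and a fold-`f` domain on
  the log scale. With fold-6 domains the two modes are ≈ 2.6 log₂ units
  apart against Poisson noise of ~0.07, which is why recovery at
  1-window resolution is essentially exact.
* **Merging and random domains.** Called windows within 10 kb merge
  into domains (gaps absorbed; idempotent). The null is a uniform
  sample of windows pushed through the same merge; at the published
  sampling fraction (35,000/272,566 ≈ 12.8%) the expected merged-domain
  count follows the Bernoulli run formula N·p·(1−p)², which the tests
  check against direct enumeration.
* **Composite profiles.** Probe-trend plots rescale each domain to 20
  interior bins plus five 1-kb flank bins per side; bin values are
  overlap-weighted means of window log₂RPKM, averaged across domains.
  Regions shorter than one bin contribute their single mean to all
  interior bins.
* **Promoters.** ±500 bp around the strand-aware TSS. FPKM classes are
  left-closed: < 0.1 not expressed, [0.1, 1) low, ≥ 1 high — the
  boundary values are assigned upward because the published interval
  notation overlaps at the cut points.

# CpG-tiled differential methylation

* **Tiling.** Consecutive windows of exactly 100 CpGs equalize the
  information content per test unit; tile spans are [first CpG, last
  CpG + 1). Trailing CpGs short of a full tile are dropped. Tiles need
  ≥ 10 observed cytosines (Σ meth + unmeth) in *every* sample.
* **Percentages.** The default per-tile percentage is the unweighted
  mean of per-CpG methylation percentages over covered CpGs
  ("per-base-mean"), matching bisulfite-pipeline convention; a pooled
  Σmeth/Σtotal mode is provided for sensitivity analysis. The two
  differ exactly when coverage is uneven across CpGs.
* **The test.** Per tile, a beta-binomial likelihood-ratio test of
  equal group means over the per-CpG × replicate observations, with a
  common per-tile dispersion φ estimated by method of moments from the
  scatter of per-CpG proportions around their group means, floored at 0
  (pure binomial), and a 1-df χ² reference. Two design points deserve
  emphasis. First, the test operates at per-CpG resolution rather than
  on per-replicate totals: a 100-CpG tile at two replicates per group
  yields ~400 observations for the dispersion estimate, which is what
  makes the χ² reference trustworthy — a dispersion estimated from four
  replicate totals is either hopelessly noisy (within-group centring)
  or absorbs the very signal under test (pooled centring), and
  simulation showed both variants badly mis-calibrated at 2v2. Second,
  the MoM centres on group means so that a true difference does not
  inflate φ and eat the power of large effects; under the null this is
  indistinguishable from pooled centring. The acceptance suite verifies
  type-I error within [0.03, 0.07] at α = 0.05 over ~2,000 null tiles
  at dispersion 0.02 and 30× coverage, p-value uniformity by KS, and
  power ≥ 0.8 for planted 30-point shifts.
* **Calling and merging.** DMR = BH-adjusted p < 0.05 and |Δ| ≥ 20
  percentage points. The published analysis does not state its cutoffs;
  0.05/20 were chosen once, the 20-point gate matching the ">20%
  methylation difference" convention the same study applies to its
  UHRF1 comparison set, and both are arguments. Same-direction DMRs
  within one tile-equivalent gap (default: the median DMR tile span,
  bridging one dropped or non-significant tile) merge into domains;
  hyper and hypo never merge.
* **Clustering.** Ward (ward.D2) on Euclidean distance of the
  per-genotype difference matrix, cut at k = 2 within each direction;
  the cluster whose single-knockout mean difference is closer to its
  double-knockout mean is "common", the other "unique". k = 2 encodes
  the common/unique dichotomy the display is meant to show; ties (e.g.
  identical columns) label everything common.

# Differential expression

Median-of-ratios size factors (computed over genes with nonzero counts
in all samples, rescaled to geometric mean 1) feed a per-gene NB Wald
test: group means of normalized counts give log₂FC, the dispersion is a
method-of-moments estimate from the pooled within-group variance,
floored at 10⁻⁸ and shrunk 50/50 toward a 1/mean trend fitted across
genes — a deliberately simpler stand-in for full empirical-Bayes
machinery, validated by properties (null BH fraction, bias, exact
group-swap antisymmetry) rather than numeric identity with any existing
tool. The contrast is tied to sorted group labels with an explicit
`reference` argument, which is what makes label swaps negate log₂FC
exactly. DEG calls additionally require BH-adjusted p < 0.05 beside the
published log₂FC ≥ 1.5 filter; the published text uses both "≥" and ">"
in different places, and the weak inequality was chosen (a `strict`
flag flips it). Down-sampling to a fixed depth (default 1.9 M reads,
the published cross-dataset depth) is a true multivariate
hypergeometric draw, so column totals land on the target exactly. ERV
quantification removes ERVs whose interval gap to the nearest gene is
strictly below 2 kb (touching counts as distance 0; exactly 2,000 bp is
retained) and reports remaining counts as a percentage of the library.

Known limitation: with a large, strongly asymmetric DE fraction
(≈ 40% of genes shifted one way) median-of-ratios absorbs part of the
shift into the size factors and log₂FC is biased toward zero — an
inherent property of the normalization, visible in simulation and kept
out of the study conditions (default truth: 50 of 300 genes).

# Moderated protein differential abundance

Columns are median-centred (global shifts cancel in contrasts). The
per-protein pooled within-group variance s² (d df) is shrunk toward a
prior (d₀, s₀²) estimated by matching moments of log s²; the trigamma
inversion uses Newton iteration (50 steps, tolerance 10⁻¹⁰). Posterior
variance (d₀s₀² + ds²)/(d₀+d) gives a t statistic on d₀+d df. The two
analytic limits are exact: d₀ = 0 reproduces the ordinary pooled t-test
and d₀ = ∞ a z-test against s₀ — both are pinned in tests to 10⁻⁹, and
the prior estimates are cross-checked against an independent
empirical-Bayes implementation. Calls gate on *raw* p < 0.05 with
|log₂FC| ≥ 0.3, exactly the published operating point for the oocyte
TMT proteome; gating on unadjusted p is unusual and deliberately
documented rather than silently "corrected".

# Integration layer

Overlap enrichment builds the 2×2 hit/miss table for a query set
against a background (typically random domains) and applies a
two-tailed Fisher exact test — two-sidedness by summing all tables with
point probability ≤ the observed one, the convention of the standard
implementation, verified against exhaustive hypergeometric enumeration
for every table with total ≤ 30 — or a χ² test that falls back to
Fisher whenever an expected cell drops below 5. Bonferroni
multiplication by the caller's family size is capped at 1. The barcode
worm evaluates, at every rank of the transcript log₂FC ordering, the
density of a protein set inside a centred rectangular window of width
0.25·N relative to its genome-wide density (1 = uniform); the
rectangular window replaces an unpublished weighted moving average, so
its acceptance is property-based (flat ≈ 1 under uniformity, > 5 at the
top rank for a top-5% set, integral ≈ N). Set positions are tested with
a rank-sum test (normal approximation with tie correction), one-sided
in the set's nominal direction. Rank correlations (methylation
difference vs expression log₂FC, transcript vs protein log₂FC) use
Spearman ρ with average-rank ties and a two-sided t approximation.

# What the simulators emulate — and what they do not

Each generator is a pure function of (configuration, seed); reruns are
byte-identical, ChIP libraries sum exactly to the requested read
number, and written truth round-trips through the JSON manifest.

* `simulate_chip()` draws multinomial window counts with in-domain
  weight × fold and uniform input, plus optional artifact windows with
  inflated input weight. It emulates window-level coverage, not reads:
  no fragment-length effects, no mappability structure, no IgG channel.
* `simulate_bisulfite()` draws per-CpG coverage ~ Poisson and
  methylated counts ~ binomial with beta-distributed per-CpG rates
  (mean m, dispersion φ; a = m(1−φ)/φ, b = (1−m)(1−φ)/φ; φ = 0 is pure
  binomial). It emulates replicate overdispersion and group shifts, not
  bimodal oocyte methylation landscapes, CpG-context differences or
  conversion error.
* `simulate_rnaseq()` draws NB counts around log-normal baselines with
  geometric-mean-centred size factors; the default truth is 90% up /
  10% down, mirroring the up-regulation bias expected when a repressor
  is lost. No length effects or isoforms.
* `simulate_proteome()` couples protein log₂FC to transcript log₂FC
  through normal scores with Pearson r = 2·sin(πρ/6) — the exact
  bivariate-normal relation between Pearson and Spearman correlation —
  so the expected Spearman ρ equals the target (default 0.43, the
  published transcript–protein coupling at n = 2,933 shared genes)
  regardless of either marginal. Replicates add Gaussian noise; there
  is no missingness, no batch structure across TMT fractions.

Passing tests on these generators therefore demonstrate statistical
correctness of the machinery under the stated models, not robustness
to every artifact of real libraries.

# Problem sizes and numerical conventions

The test and acceptance runs use desk-scale conditions chosen once: a
3 × 5 Mb genome with 30 fold-6 domains at 10⁶ reads for domain
recovery; ~2,000 null 100-CpG tiles (dispersion 0.02, 30×, 2v2) for
DMR calibration and 200 planted 30-point tiles for power; 5,000 genes
at baseline 100, dispersion 0.05, 4v4 for the DE engine; 3,000
proteins, 5v5, for moderated-t size; n = 2,933 for coupling recovery;
and a 0.2× pipeline scale for the end-to-end determinism check. All
coordinates are 0-based half-open; BED is the only interval interchange
format; every stochastic function requires an explicit seed and derived
stage seeds stay below 2³¹. Optimizations: the beta-binomial MLE of the
mean is a 1-D `optimize` (tolerance 10⁻⁷) per group; ties in clustering
are broken toward the lower row index; degenerate inputs (empty groups,
zero-coverage tiles, constant vectors) return NA or error with an
explicit message rather than propagating silently.
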