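---
title: "Methods: modelling oncohistone-driven H3K27me3 redistribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling oncohistone-driven H3K27me3 redistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncochrom)
```

## The model and its assumptions

The central object of this package is a local, concentration-dependent
account of PRC2 activity in cells expressing a K27M oncohistone. At every
genomic position, two factors act antagonistically *in cis*: pre-existing
H3K27me3 (`x`), which allosterically stimulates PRC2, and incorporated
oncohistone (`y`), which inhibits it. The resulting mutant H3K27me3 level
(`z`) is modelled as a Taylor-style polynomial in the single difference
variable `d = x − y`:

$$Z = A_0 + A_1 \sum_{n=1}^{7} A_{n+1} \, (x-y)^n$$

All signals are input-normalized log2-ratio ChIP values at 1 kb resolution.
Key assumptions baked into this form:

* **Locality** — `z` at a bin depends only on `x` and `y` at that bin; no
  spreading terms, no long-range contacts. This is appropriate for a genome
  (like the worm's) with little far-cis H3K27me3 spreading and no DNA
  methylation.
* **Shift invariance** — the model sees only `d = x − y`; adding a constant
  to both inputs leaves `Z` unchanged. `evaluate_dependency()` computes the
  inner polynomial by Horner's rule so that `d = 0` yields exactly `A_0`
  with no floating-point residue.
* **Identifiability** — the published `(A_1, A_2..A_8)` split is redundant:
  only the products `B_n = A_1 A_{n+1}` (and `B_0 = A_0`) are identified.
  `fit_dependency()` therefore fits the reduced form
  `Z = B_0 + \sum B_n d^n` by ordinary least squares and reports `B`,
  mapping it into the `A` slots with `A_1 = 1`. The original spreadsheet
  optimization over the redundant form cannot be reproduced stably; OLS
  spans the identical function space and is exact.

Numerical choices in the fit: powers of `d` are computed on the centered and
scaled variable `u = (d - \bar d)/s_d` (a raw degree-7 Vandermonde design is
ill-conditioned) and coefficients mapped back through the binomial shift
matrix; standard errors go through the same linear map. A rank-deficient
design (all `d` equal, or too few distinct values) raises a fit error naming
the degeneracy rather than returning garbage.

Two R² conventions exist and differ across datasets. `goodness_of_fit()`
reports the squared Pearson correlation between predictions and
observations as the primary `r_squared` (matching the "R² correlation"
wording of the original optimization), alongside the regression variant
`1 − SSE/TSS`. They coincide for an OLS fit with intercept evaluated on its
own training data, but not when a fitted model is applied to another
dataset — which is exactly the cross-application this package supports
(e.g. an H3.3-mode fit applied to H3-like-mode data).

## Signal processing conventions

* Coordinates are 0-based half-open everywhere (bedGraph convention);
  trailing partial bins are real bins (`ceiling(length / bin_size)`).
* `bin_coverage()` interprets per-bin read counting as the **maximum
  per-base fragment depth** inside the bin — the only reading that is
  well-defined for fragments spanning bin edges. A fragment-overlap count
  is available via `stat = "count"`.
* Replicates are merged additively (bin values and read totals summed),
  which is exact for count statistics and a documented approximation for
  the max statistic.
* Equal-total scaling happens **before** input normalization (the order is
  not dictated by the source procedure; this choice is fixed and
  documented here).
* Input normalization: `delta` (subtraction, robust to low-count bins) or
  `logratio` (`log2((ip+pc)/(input+pc))`, default pseudocount 1 to avoid
  infinities on empty input bins).
* Smoothing is a centered running mean (default window 5 bins) with edge
  truncation; chromosome boundaries are never crossed. The smoothing method
  was not specified by the source procedure; a running mean is the simplest
  edge-safe choice and the window is exposed everywhere it matters.
* Re-binning takes the mean of constituent fine bins, partial trailing
  groups averaged over members present.

## Domain classification

Presence of the mark in a condition is `value > τ` (default `τ = 0` on a
log-ratio track, i.e. enrichment over input), cleaned by dropping presence
runs shorter than `min_bins` (default 5) and then bridging gaps of at most
`max_gap` bins (default 2) — in that order. No thresholds were published
for the original domain calls, so all three are parameters; the defaults
produce blocky domains on the synthetic fixtures. Presence is intended to
be decided on smoothed tracks (the pipeline smooths before calling).
Categories: autosomal bins become *i maintained* (present in both),
*ii lost* (wild type only) or *iii never*; X bins with retained presence
become *iv X-maintained*, all other X bins *iii*. A bin present only in the
mutant (a gain) falls into *iii*: the classification defines no gain
category, and adding one would change the published four-way partition.

## Clustering

`cluster_bins()` reproduces the heatmap analysis: agglomerative clustering
of 10 kb bins on the (wt H3K27me3, oncohistone, mutant H3K27me3) triplet,
autosomes and X separately. The original tool's settings were not recorded;
the defaults here are distance `1 − Pearson` across the three columns and
average linkage (the tool's common defaults), `k = 6` clusters per
partition, columns unstandardized (all three are comparable log-ratio
signals). Euclidean distance, complete linkage and z-scoring are available
as options. Rows constant across the three columns have undefined
correlation; their distance to other rows is defined as 1. Clustering is
fully deterministic for a fixed matrix.

## Expression integration

DE labels use the strict thresholds FDR < 0.05 and fold change > 2; the
downregulated side is the symmetric FC < 1/2 (the source states only
"fold change > 2" but displays both directions; the symmetric reading is a
documented assumption). Boundary genes are `ns`. Quintiles are assigned on
wild-type expression over **all** genes in the table (expressed-only
filtering was not specified), sizes differing by at most one with
remainders to the lowest quintiles and ties broken by gene id. Metagene
profiles rescale each gene body to 100 slots (point-sampling the bin at
each slot center) with 500 bp flanks at native bin resolution; strand is
ignored throughout, because none of the in-scope signals is
strand-resolved (a flip option would be the natural extension). ΔH3K27me3
per gene is the difference of gene-body bin means. The change correlation
reports Spearman (primary) and Pearson coefficients with a seeded
label-permutation p-value.

## Ploidy calibration

DNA content is inferred from integrated DAPI intensity by linear regression
anchored at two populations of known ploidy: diakinesis-stage oocytes (4n)
and endoreduplicated intestine nuclei (32n). The regression runs
intensity-on-content — the contents are exact, the intensities noisy — and
is inverted for estimation; with exactly two distinct anchor contents the
line interpolates both group mean intensities, so the anchors are recovered
exactly regardless of within-population noise. No zero intercept is forced
(background fluorescence exists). Pooled calibration is the default;
per-gonad calibration was not specified in the source and is left to the
caller by subsetting.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, at
1/10 genome scale so that default runs finish in under a second:

* **Genome**: five autosomes (1.65 Mb each) plus one X (1.75 Mb), 10 Mb
  total, X fraction 17.5% — proportions of the worm genome, scaled down.
* **Wild-type H3K27me3**: X uniformly at log-ratio 2.0; autosomes with
  alternating domain/background blocks (geometric lengths, mean 20 kb,
  35% coverage, domain level 1.5, background 0). A single length parameter
  reproduces the blocky domain structure.
* **Oncohistone**: domain centers sampled with probability proportional to
  `max(wt) − wt` (soft anti-placement rather than hard exclusion), 40%
  autosomal coverage, level 1.5. H3.3 mode sets the X to
  `0.1 × autosomal mean` — the depletion ratio holds by construction on the
  noiseless signal. H3-like mode keeps the same centers, widens domains
  2-fold and raises the X to the autosomal mean (no depletion). No
  quantitative rule for X retention was published; a uniform level equal to
  the autosomal mean is the simplest reading of "more even distribution".
* **Mutant H3K27me3**: the exact dependency-model image of the (noisy)
  wild-type and oncohistone tracks, plus residual Gaussian noise
  (SD 0.1). Track noise is additive Gaussian (SD 0.25) on the log-ratio
  scale, where additive noise is natural. The two noise levels are the ones
  the validation criteria state (track noise 0.25 for domain-recovery
  accuracy, residual noise 0.1 for fit recovery), kept as separate
  configuration fields.
* **Genes**: 2000 genes placed non-overlapping on one strand, lengths
  uniform 0.5–5 kb, wild-type expression log-normal
  (meanlog 4, sdlog 1.5). 500 DE genes are drawn across quintiles with
  probabilities (0.05, 0.35, 0.35, 0.15, 0.10) — planting 70% in II+III.
  Each DE gene's |log2 FC| lies in [1.2, 3] with magnitude increasing in
  the rank of |ΔH3K27me3| and sign opposite to ΔH3K27me3; a sign-only
  coupling would not yield the observed anti-correlation when nearly all
  genes lose the mark (the genome-wide direction of change), so the planted
  relationship is monotone. `ns` genes get |log2 FC| ≤ 0.9 and FDR ≥ 0.05,
  so the DE filter recovers the planted labels exactly.
* **DAPI**: intensities normal around `200 + 50 × content` (arbitrary
  units) with CV 0.1 per population; endomitotic content 64n (many-fold
  above the 4n reference, within the range implied by massive
  endoreduplication); 50 nuclei per population.

One master seed feeds a named substream per generator, so outputs are
bit-for-bit reproducible and adding a generator never perturbs the others.

### What a green test does and does not establish

The generator plants exactly the dependencies the analysis is designed to
detect; passing tests establish that the implementations are correct and
self-consistent (oracle equivalence, exact recovery in noiseless limits,
statistically calibrated recovery under noise). They do **not** establish
anything about real chromatin: real ChIP signal has position-dependent
bias, non-Gaussian noise, unknown domain-length distributions, and the real
dependency between the marks need not be a degree-7 polynomial. The default
Spearman anti-correlation of −1 at coupling strength 1 is likewise a
property of the planted world, not a prediction for data.

## Known limitations

* Read alignment, SAM parsing, and differential-expression model fitting
  are out of scope: the package consumes interval placements, bedGraphs and
  a statistics-bearing gene table.
* The max-depth bin statistic under replicate merging is approximated by
  summation (exact only for the count statistic).
* The published 1 kb bin count of the original genome build (100,281) is
  not reproducible from stated chromosome lengths under any obvious tiling
  rule; fits here report their own `n_bins` instead.
* Heatmap rendering, GO-term enrichment and application to external
  mammalian datasets are intentionally absent; the model operations
  (`fit_dependency()`, `goodness_of_fit()`) support such data unchanged.
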