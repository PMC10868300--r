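---
title: "Copy-number inference from methylation array intensities: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number inference from methylation array intensities: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcnv)
```

## The problem

Illumina-style methylation arrays measure, for every probe *i*, a
methylated (*M*) and an unmethylated (*U*) fluorescence intensity. Their
sum `I_i = M_i + U_i` reflects how much template DNA was present at the
locus, and is therefore a proxy for its copy number. Extracting usable
copy-number profiles from `I` is hard because the dominant variation is
technical: whole-genome amplification after bisulfite conversion is not
uniform across the genome, and its biases differ between experiments and
batches. methylcnv implements a complete workflow that removes this
structure, summarizes the residual signal into genomic bins, segments
those bins into copy-number levels, and screens genes for focal
amplifications and homozygous deletions with a sample-specific null model.

## Tangent normalization

The central assumption is that the technical bias profile of a query
sample lives in the span of a panel of copy-number neutral control
samples that went through comparable processing. The query's
log2-intensity vector is regressed (ordinary least squares, no intercept)
on the control panel's log2 intensities:

```
R_i = log2(I_qi) - sum_c a_c * log2(I_ci)
```

Key choices, and why:

* **Log space.** Both bias and copy number act multiplicatively on
  intensities, so in log space the bias is linear and exactly removable.
  The legacy variant (`fit_tangent_raw()`) fits raw intensities and only
  logs afterwards; it is retained because it clamps negatively fitted
  control intensities to 1 before the log, which visibly inflates noise —
  the comparison is reproduced by the test suite and the acceptance
  script.
* **No intercept, unconstrained coefficients.** An intercept would absorb
  genuine ploidy shifts, which are instead handled by baseline correction
  at the bin level. Coefficients may be negative; real panels routinely
  produce a few negative loadings. A consequence of omitting the
  intercept is that a global rescaling of the query is only absorbed
  exactly when the constant vector lies in the control span; with
  realistic panels the residual is small and baseline correction removes
  what remains.
* **Floor = 1.** Intensities are clamped to at least 1 before `log2`,
  keeping zero-signal probes finite without materially affecting normal
  signal (typical intensities are in the thousands).
* **Minimum-norm fallback.** A rank-deficient panel (duplicated or
  collinear controls) is solved by the SVD minimum-norm solution with a
  warning rather than an error.
* **Panel hygiene.** At least 16 controls are recommended (a warning is
  issued below that); a query appearing in its own panel by sample id is
  an error, and an exact-duplicate control column triggers a warning.

The per-sample quality metric is the noise parameter,

```
noise = sum |R_{i+1} - R_i| / (sqrt(2) * (n - 1))
```

over neighboring probes within chromosomes. Under independent Gaussian
probe noise this estimates the per-probe standard deviation; samples
above 0.6 should be excluded (`flag_noisy_sample()`).

## Genomic binning and baseline correction

Each chromosome arm is tiled into 50 kb windows; windows without probes
are dropped, and any bin with fewer than 15 probes or a span under 50 kb
is merged into whichever same-arm neighbor has fewer probes, repeatedly,
until all bins satisfy both minima. Merging never crosses a centromere:
copy-number contiguity breaks there, so arms are the natural unit. Ties
between neighbors merge toward the lower coordinate, and deficient bins
are resolved in ascending coordinate order, which makes the map fully
deterministic. The minimum-size criterion is evaluated on the merged
bin's genomic span. An arm whose total probes cannot reach the minimum
keeps one bin flagged `deficient` rather than losing its probes; the
inverse-variance weighting naturally de-emphasizes it downstream. Bins
depend only on the manifest, genome and parameters — never on
intensities — so they are identical across samples, which is what makes
cohort summaries and referential segments well-defined.

The bin value is the median probe log2-ratio; the per-bin unbiased probe
variance is kept for weighting. Baseline correction then determines the
copy-neutral level: the profile is shifted by the centering factor `s*`
minimizing the median absolute deviation of bin values about zero,
searched in [-1, +1]. Because that objective is piecewise linear with
kinks only at bin values and midpoints of bin-value pairs, `s*` is found
exactly from that candidate set (a two-stage grid is used above 1500
bins); ties prefer the smallest shift, which makes the operation exactly
idempotent. The median-based criterion keeps the correction anchored on
the copy-neutral majority as long as at least half the genome is neutral;
profiles violating that assumption (e.g. whole-genome duplications) will
be centered on the dominant state instead — a known limitation shared by
the method family.

Bin weights are `1 / max(variance, 1e-4)`; the floor stops near-constant
bins from dominating the segmentation. Single-probe bins take the
profile's median variance. By default the variance comes from the query's
own probes; `bin_weights(variance = bin_variance_from_controls(...))`
switches to control-panel variance, for users who prefer a
sample-independent weighting.

## Weighted circular binary segmentation

Segmentation treats each arm as a circle and finds the arc maximizing a
weighted two-sample statistic between the arc and its complement:
weight-weighted means on both sides, pooled weighted residual variance,
`n - 2` degrees of freedom. At unit weights this reduces exactly to the
classical pooled two-sample t, which is what the exhaustive-enumeration
oracle in the test suite checks. Significance is assessed by permutation:
(value, weight) pairs are shuffled jointly, and the split is accepted
while `p < alpha` with `p` computed under the add-one rule. Accepted
splits are applied recursively; each resulting piece must hold at least
`min_width` bins. Inside the recursion the permutation loop stops as soon
as the exceedance count makes `p >= alpha` certain — a pure speed
optimization that cannot change any decision — while the standalone
`permutation_pvalue()` always completes the full loop. An optional
`undo_sd` pass merges adjacent segments whose means differ by fewer than
the given number of pooled standard errors.

Defaults (`alpha = 0.01`, `n_perm = 10000`, `min_width = 2`, undo off)
follow common practice for permutation-calibrated CBS. Down-weighting
high-variance bins makes boundary recovery measurably more robust when a
few outlier bins are present; the acceptance script quantifies this on
100 paired replicates.

One caveat at small problem sizes: a 2-bin focal event on an arm of ~40
bins cannot reach `p < 0.01` under permutation, because roughly 2/n of
shuffles reproduce an equally extreme adjacent pair by chance. This is
inherent to permutation CBS, not an implementation artifact; focal events
are the responsibility of the bootstrap-calibrated focal module, while
segmentation targets arm-scale structure.

## Focal events: k-means states and segmented block bootstrap

Focal calling builds a sample-specific null for gene-level values:

1. **States.** One-dimensional k-means (k = 3) on bin values, centers
   initialized at the 10th/50th/90th percentiles and refined by Lloyd
   iterations — deterministic, so the seed only governs the bootstrap
   sampler. Lowest center = loss, highest = gain. Fewer than three
   distinct values degenerates to all-balanced with a warning.
2. **Bootstrap.** Each maximal same-state run of bins is rebuilt by
   concatenating 500 kb blocks drawn uniformly with replacement from all
   genome-wide windows of that state, trimmed to the run's bin count;
   100 iterations are pooled. Resampling within states preserves both the
   local autocorrelation and the state composition of the profile, so the
   pooled values form an honest null for "how extreme can a bin look in
   this sample".
3. **Thresholds.** The deletion/amplification thresholds are the `tail`
   and `1 - tail` quantiles of the pool; `tail = 0.005` (a 99% two-sided
   interval) is a declared default, exposed as a parameter. Noisier
   samples automatically get wider thresholds — the property that makes
   fixed global cutoffs unnecessary.
4. **Calls.** A gene's value is the median log2-ratio of probes inside
   its (1-based, inclusive) interval. Values strictly beyond a threshold
   are called; the empirical p-value is the add-one one-sided tail of the
   pool on the side of the deviation, so it is never exactly zero.

Two documented resolutions of underdetermined details: p-values are
computed against the pooled bin-value distribution (not against
length-matched per-gene resampling statistics), and bootstrapped values
are not re-segmented before threshold derivation.

## The synthetic-data generator

Every stage is testable without downloads because the generator emulates
exactly the structure the method is built to remove:

```
I_is = alpha_i * (CN_is / 2) * exp(F_i . lambda_s) * eps_is
```

lognormal probe affinities `alpha` (median intensity 2000, sdlog 0.6), a
rank-k technical factor structure `F lambda` shared between controls and
queries (k = 3, loading sd 0.3 — comparable in log2 magnitude to the
measurement noise, as real batch effects are), lognormal measurement
noise (`sigma = 0.25`), and copy number acting multiplicatively through
`CN/2`. Homozygous deletions use a residual factor of 0.05 instead of 0,
standing in for background fluorescence and tumor impurity. Probe
placement mixes a uniform background with dense clusters, mimicking
CpG-island-centric designs. Defaults — 2 chromosomes of 10 Mb, 4000
probes (about 220 bins), 20 controls — keep a full pipeline run around a
second per sample, so the test suite and acceptance script run at desk
scale (50-query experiments in well under ten minutes).

What the generator does **not** model: probe type I/II intensity shifts,
GC bias, bisulfite-conversion chemistry, FFPE artifacts, germline CNVs in
the panel, or tumor purity below 100%. Consequently, passing tests
demonstrate the statistical machinery (bias removal, calibration,
thresholding) under the model's own assumptions — not performance on real
tumors, where purity and unmodeled noise reduce sensitivity well below
the synthetic operating point.

One scale effect deserves emphasis. On a real array a focal event spans a
vanishing fraction of ~15 000 bins, so it cannot distort its own
bootstrap null. On a 220-bin synthetic genome, a multi-bin event is 1-2%
of the genome — several times the 0.5% tail — and would mask itself.
`place_genes()` therefore sizes synthetic genes to the probe-dense core
(about 45% of the probes, at least 10) of a single probe-rich bin: the
gene-level median rests on a dozen or more probes, as CpG-island genes do
on real arrays, while an event confined to it never dominates the bin
median feeding the null. This is the faithful desk-scale analogue of the
real operating regime, not a tuning of the method.

## Cohort summaries and interoperability

Per-sample segment tables are merged by taking the union of all
breakpoints per chromosome ("referential segments"); each sample's
segment mean is propagated onto every referential segment it covers and
classified as gain (> 0.1), loss (< -0.1) or balanced — thresholds in
line with common GISTIC practice, applied to segment means rather than
bin values. Gene-level comparisons across platforms use the gene-wise
weighted mean of overlapping segments' log2-ratios, weighted by
intersection length. Segmentations are written in the IGV/GISTIC SEG
dialect (1-based inclusive coordinates, 4-decimal means) and read back
losslessly at that precision. `run_cohort()` isolates per-sample
failures, records every parameter and seed in `run_manifest.json`, and —
given fixed seeds — produces byte-identical output across reruns
(figures are written separately by `genome_plot()`, since image file
formats embed timestamps).

Numbers are printed 1-based inclusive in every text format; internally,
bins and segments use half-open intervals and gene intervals are closed.

## Worked example

```{r example, eval = FALSE}
library(methylcnv)

cnvs <- data.frame(query = 1, chrom = "chr1", start = 1e6, end = 4e6, cn = 3)
cfg  <- sim_config(n_queries = 1, cnvs = cnvs, seed = 42)
sim  <- simulate_manifest(cfg)
coh  <- simulate_cohort(cfg, sim$manifest)

res <- run_cohort(coh$queries, coh$controls, sim$manifest, sim$genome,
                  out_dir = "results", config = list(seed = 7))
res$qc
res$samples$query01$segments
```

The gained 3 Mb region is recovered as a segment with mean near
`log2(3/2) = 0.585`; the QC table reports the per-sample noise parameter
and baseline shift.

## Known limitations

* Baseline correction assumes a copy-neutral majority of the genome.
* Sex chromosomes are processed like autosomes; the control panel's sex
  composition shifts their baseline, so calls there need a matched panel.
* Focal thresholds calibrate to the sample's own bin distribution; in a
  genome dominated by aberrations the null widens and sensitivity drops.
* No tumor-purity or integer-copy-number modelling: reported values are
  log2-ratios of mixtures.
* The permutation reference distribution is exact but O(n^2) per
  permutation; very large bin counts should use fewer permutations or
  larger `alpha` with `undo_sd`.
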