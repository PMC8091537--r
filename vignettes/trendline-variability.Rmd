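---
title: "Trendline variability screening: methods and design notes"
author: "tlv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trendline variability screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlv)
```

## The problem

Differential expression pipelines compare groups, but a nominally
homogeneous "control" group is rarely homogeneous: a few individuals may be
mounting an interferon response to a recent or latent viral exposure, sex
chromosomes make some genes bimodal, and elevated white-cell counts shift
whole expression programs. Such intra-group structure inflates variance
estimates and can silently bias downstream contrasts, yet standard outlier
handling either removes those samples or leaves the structure undetected.

`tlv` screens a gene × sample matrix of non-negative normalized counts
(TPM-like) *within* a group and reports which genes diverge from the
group's expression envelope, which genes co-vary as modules, and which
individuals carry those modules.

## The model and procedure

**Rank-order trendlines.** For each gene, the counts of the `n` samples are
sorted ascending; the resulting curve is the gene's *trendline*. If the
samples were exchangeable draws from a normal distribution, the trendline
is simply the sample's order statistics, which lie close to a straight
line against rank `1..n`. The coefficient of determination of the fit of
value against rank,

\[ R^2 = \mathrm{cor}(x_{(i)}, i)^2, \]

therefore measures how "normal-envelope" a gene is; tailed genes — flat
through the middle ranks with a sharp rise in the top quartile — have low
\(R^2\), high excess kurtosis, and large range/Q3 and range/median ratios.

**Minimum Value Adjustment (MVA).** Counts span roughly five orders of
magnitude across genes, so raw dispersion measures are dominated by the
mean (heteroscedasticity). MVA divides each gene's counts by that gene's
smallest count, anchoring every trendline at 1. It is a positive per-gene
rescaling: sample ordering, CV, skewness, kurtosis, \(R^2\) and all range
ratios are unchanged, while the mean and SD shrink by exactly the divisor.
These invariances are asserted by the test suite. A median-of-ratios
size-factor step (the classical sequencing-depth correction) is available
before MVA and can be disabled for input that is already depth-normalized.

**The statistics suite.** Per gene the package reports mean, median,
sample SD, CV (%), min, max, range, max/min, inclusive quartiles,
range/median, range/Q3, bias-corrected skewness and excess kurtosis, the
rank-regression slope and \(R^2\), and quartile-segment slopes. Two
conventions are pinned deliberately to the spreadsheet formulas that most
laboratory workflows use:

* percentiles use inclusive linear interpolation, plotting position
  \(h = p(n-1) + 1\) (identical to R's `quantile(type = 7)`);
* skewness is \(\frac{n}{(n-1)(n-2)} \sum z_i^3\) and excess kurtosis
  \(\frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum z_i^4 - \frac{3(n-1)^2}{(n-2)(n-3)}\),
  the bias-corrected estimators, rather than raw moment ratios.

Both are independently cross-checked in the tests against `e1071`'s
type-2 estimators and direct `lm()`/`quantile()` computations.

**Quartile-slope ratios.** Tailedness is localized by fitting separate
least-squares slopes on the first `round(n/4)` ranks (Q1), the middle
ranks (Q2+Q3) and the last `round(n/4)` ranks (Q4); the ratios
Q1/(Q2+Q3) and Q4/(Q2+Q3) approach 1 for a linear trendline and grow
large when a tail pulls away. For `n = 35` the default split is 9/17/9;
the split is configurable (`quartile_ends`) because no single convention
exists for `n` not divisible by 4, and the analysis is recommended for
`n >= 16` so each segment holds enough points for a stable fit. A flat
middle segment makes the ratios infinite; such genes are flagged
(`flat_mid`) and infinities deliberately sort *above* all finite values
in top-N selection, since a flat core with a moving tail is the extreme
form of the pattern the ratio measures.

**Selection and modules.** `top_n_by_stat()` takes the `n = 300` genes
with the largest value of any statistic (ties at the boundary are all
included, then order is stabilized by gene identifier, making selection
deterministic and permutation-invariant). `calibrate_thresholds()`
reproduces the interactive "tighten the correlation cutoffs until the
subset is small enough" workflow as a bisection: both the positive
threshold `hi` and the negative threshold `lo` move jointly along matched
empirical quantiles of each gene's most extreme positive and negative
partner correlation, until the selected set is the smallest achievable at
or above the target size. Matched quantiles are the default because the
original manual procedure gives no rule for balancing the two tails;
single-tail policies and explicit thresholds are available. Correlations
are computed blockwise so the full ~10^4 × 10^4 matrix never
materializes.

**Positional ranks and the scoring function.** Reversing the trendline
gives positional ranks: per gene, the sample with the highest count holds
position 1. For each individual, `collect_individual_genes()` starts at
cutoff `k = 1` and grows `k` until at least `min_genes = 1000` genes are
collected in which that individual holds position ≤ `k`. This is the
minimal reading of "collect at least 1000 positionally ranked genes per
individual"; it is isolated behind one function so alternative scoring
rules (e.g. weighted positions) can be swapped in. The collected genes
are then filtered, inclusively (≥), by the top-300 thresholds of
range/median, range/Q3, excess kurtosis and the Q4 slope ratio, and each
filtered list is tested for over-representation.

**Enrichment.** `ora()` is a local hypergeometric over-representation
test with Benjamini–Hochberg adjustment across sets, standing in for
web-database pathway queries so the screen runs offline and
reproducibly. The background universe is the analyzed (protein-coding,
filtered) genes intersected with the collection's annotation space —
restricting to analyzed genes is what makes the test answer "is this
individual's divergent-gene list concentrated in a pathway" rather than
"is this pathway expressed". An individual is flagged when any filtered
list reaches a best FDR ≤ 1e−15, a deliberately conservative benchmark at
which random gene lists essentially never qualify; it is a parameter
(`fdr_flag`). Absolute FDR values from external databases use different
machinery and are not comparable beyond order of magnitude.

## Input filtering

Three steps precede scaling, in a fixed order:

1. restriction to a user-supplied protein-coding list (non-coding
   transcripts dilute enrichment); the discarded rows are kept in a
   separate matrix;
2. merging of multi-location (CNV) gene rows under canonical symbols by
   element-wise **sum**, which conserves total signal; an alias that
   would capture an unrelated existing gene is an error;
3. low-count cleanup: values `< 0.5` are floored to 0 *first*, then genes
   with post-replacement mean `< 0.5` are removed. The order matters — a
   gene like `(0.3, 0.6, 0.7)` is removed under floor-then-mean but kept
   under mean-then-floor — and is pinned by test.

Whether CNV merging should precede or follow the protein-coding filter is
not dictated by anything in the method; the pipeline applies filter →
merge, and both functions are exposed so the other order is available.

Genes that still contain zeros after flooring have no positive minimum
for MVA. They are divided by their smallest *positive* value (zeros stay
0) and flagged `zero_containing`; the flag is carried into the statistics
table so analyses with and without those genes are both recoverable.
All-zero genes are an error rather than a silent drop.

## The synthetic generator

`generate_counts()` produces matrices with the structure the method
assumes, plus ground-truth labels, so every stage is testable without any
download. Defaults describe the emulated study group:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 35 | the size of the emulated control cohort |
| `n_genes` | 8746 | retained protein-coding genes after filtering |
| `mean_log10_range` | [0, 5] | per-gene means span ~5 decades |
| `baseline_cv` | 0.2 | normal envelope: `x ~ N(mu, 0.2 mu)`, truncated at 0 |
| `tailed_module` | 14 genes, 4 affected samples, folds log-uniform [5, 50] | a coordinated induced module, elevated only in a few individuals, with gene- and sample-specific magnitude |
| `bimodal_genes` | 10 genes, high in the last 11 samples, low group at 5% of the mean | sex-linked bimodality in a mixed-sex cohort |
| `zero_inflation` | 0 | the upstream low-count filter makes residual zeros rare; raise it to stress the zero-containing path |

The affected samples are drawn at random under the seed (or fixed
explicitly); fold multipliers are drawn per (gene, sample) so the module
is coordinated but not uniform. `spike_in_reference()` adds
constant-concentration control rows with small technical noise and an
optional single aberrant library.

What the generator does **not** emulate: library-size/negative-binomial
count noise, gene–gene correlation among baseline genes, batch structure,
and mean–variance trends beyond the constant-CV envelope. Consequently
the baseline fraction of linear trendlines (R² ≥ 0.9) is higher in
synthetic data (~89%) than in real cohorts (~65–70%), where additional
biological variability erodes linearity: passing recovery tests here
demonstrate correctness of the machinery under the stated model, not
real-data sensitivity or specificity.

## Numerical choices and degenerate inputs

* Ties in both sort directions are broken by sample-identifier lexical
  order, making every permutation deterministic.
* Constant genes: SD, CV and slope are 0; \(R^2\) is *defined* as 0 with
  a `constant` flag (the correlation is undefined), keeping tables total;
  they are excluded from correlation analysis with a warning.
* Zero median (or Q3) with nonzero range makes the corresponding ratio
  infinite, flagged rather than dropped.
* Kurtosis needs `n ≥ 4`, skewness `n ≥ 3`; below that the fields are
  `NA` with a `kurtosis_undefined` flag.
* The bisection in `calibrate_thresholds()` runs 60 iterations on the
  quantile level; the selected-set size is a step function, and the trace
  (exposed in the result) is asserted monotone in the tests. A target of
  0 returns thresholds strictly beyond the observed extremes.
* Reported fold ranges follow the mixed presentation convention of
  laboratory reports — nearest integer at ≥ 10, one decimal below — with
  the raw value always retained.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the default synthetic
scenario (8746 × 35) across 20 generations for recovery of the spiked
module and affected individuals, 200 random vectors (n ∈ {8, 16, 35})
for oracle equivalence of the statistics, exhaustive enumeration of the
hypergeometric test for universes up to N = 12, and one full-scale
threshold calibration (target 500 of 8746 genes). Unit tests use smaller
matrices (300–2000 genes) chosen to keep each property sharply
attributable to one operation.

## Known limitations

* The screen characterizes *intra-group* structure; it does not adjust a
  downstream differential analysis, it informs one.
* Enrichment quality is bounded by the supplied GMT collections; the
  package ships no annotation.
* The scoring function's cutoff expansion is one defensible reading of
  "at least 1000 top-positioned genes"; weighted alternatives would need
  a replacement for `collect_individual_genes()`.
* MVA is designed for variability analysis. Differentially scaled data
  should not be fed to DGE tools expecting raw or size-factor-normalized
  counts.
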