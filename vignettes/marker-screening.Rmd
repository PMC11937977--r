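---
title: "Marker signature screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker signature screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscreen)
```

# The problem

Given bulk expression profiles labeled by group (sorted cell populations,
cell lines, experimental conditions), we want the genes *specific* to one
target group: expressed above every other group, consistently so across all
comparisons, and — when a background dataset for the tissue
microenvironment is available — not ubiquitously expressed in that
background. This vignette explains each stage of the pipeline, the
assumptions it makes, and the choices taken where the design was genuinely
open.

# Differential expression stage

Raw counts go through the standard count workflow: expression filtering
(at least 10 counts-per-million-equivalent in at least *k* samples, *k* =
smallest group size, and 15 total counts), TMM normalization, voom
precision weights, and gene-wise weighted least squares on a group-means
design (`~ 0 + Group` plus treatment-coded batch columns). Batch enters as
a fixed-effect covariate rather than by pre-correcting the matrix: count
transformations that "remove" batch also distort the mean-variance
relationship the weights depend on. The target is contrasted against each
of the *n − 1* other groups with empirical-Bayes moderation and, when a
fold-change threshold is set, the *treat*-style shifted-null test whose
p-value combines both tails conservatively. Benjamini-Hochberg adjustment
is applied within each comparison, because ranks are later taken per
comparison; pooling adjustment across comparisons would couple the lists.

Log-normalized input cannot use count-based filters or weights; it is
filtered by mean log-expression (default 1.0 on the log2 scale, in at
least *k* samples above a floor of 1.0) and tested with a mean-trended
prior variance (the limma-trend route).

Assumptions worth stating: library sizes differ only by depth and
TMM-correctable composition; counts are roughly negative-binomial so the
voom trend captures their variance; groups share a common within-group
variance per gene after weighting.

# Rank-product scoring

Each comparison ranks its genes by a statistic (p-value by default;
`logFC` ranks by decreasing magnitude). Ranks are averaged over ties — the
deterministic standard — and taken over the *common universe*, the
intersection of the filtered result tables. The rank product
`RP_g = sum_i ln rank_gi` rewards genes near the top of *every* list; the
logarithm means one bad comparison costs a bounded penalty rather than
vetoing the gene, which is the point of using rank products instead of a
plain intersection of per-comparison DEG calls.

Significance comes from a bootstrap permutation null: each comparison's
rank vector is shuffled independently (a random bijection of genes to the
observed rank multiset), `rp` recomputed, and
`score_g = P(RP_g > rp)` estimated as the fraction of `K` shuffles with
`rp` strictly below `RP_g`. Choices here:

* **K = 1000** by default: the score threshold defaults to 0.05, so a
  resolution of 10^-3 is comfortably finer; K is configurable.
* **Strict inequality, no pseudocount**, following the estimator's plain
  form; a smoothed `(r + 1)/(K + 1)` variant is available
  (`smooth = TRUE`) for users who need nonzero scores.
* **Per-gene null draws.** Each gene is compared with its own shuffled
  values. The marginal null distribution is identical across genes, so
  this matches the pooled alternative in expectation; exhaustive
  enumeration (`exhaustive = TRUE`, used in tests on toy instances) gives
  the exact, gene-independent null and is exactly monotone in RP.
* **Seed handling**: the RNG state is saved and restored, so scoring never
  perturbs the caller's stream.

## Selection and the common-DEG gate

Genes with `score < 0.05` are selected, then gated: a marker must be a DEG
common to all comparisons — BH-adjusted p below `de_alpha` (default 0.05)
and, with the default `direction = "up"`, log-fold-change toward the
target in every list. The gate is needed because permutation scores are
uniformly distributed over exchangeable null genes: the threshold alone
would always admit about 5% of the non-marker universe, which in a
2000-gene screen is dozens of false positives. Requiring per-comparison
significance removes essentially all of them while leaving genuinely
consistent markers untouched (they are, by construction, significant
everywhere). The gate is deliberately *not* applied before ranking:
ranking only pre-filtered significant genes would leave a universe of
near-exchangeable top genes in which the permutation score is again
uniform, and recall would collapse to the threshold fraction.

`keep_top`/`keep_group` force the top-N genes of designated comparisons
into the selection regardless of score, and bypass the gate — the
mechanism exists precisely to relax stringency for a comparison against a
closely related sibling group.

Only up-regulated genes are eligible by default because a signature is
meant to mark the target's presence; `direction = "any"` restores
two-sided behavior.

# Marker pools and aggregation

Pools are merged from GMT collections by union with first-occurrence
order; per-gene provenance (which source sets contributed the gene) is
kept machine-readable rather than as free text. The selection is
intersected with the pool when one is supplied; separately, pool genes are
*protected* in the SNR step, on the view that curated markers should not
be silently discarded by an automated filter. Protection applies to the
SNR step only — the pool constraint itself already controls what enters
the signature.

Across datasets: `union` (recommended for small per-dataset signatures),
`intersect` (for highly concordant datasets), or RRA. The RRA score of a
gene with sorted normalized ranks r(1) ≤ … ≤ r(m) over m lists is
`min_k P(Binomial(m, r(k)) ≥ k)`, Bonferroni-multiplied by m and capped at
1; genes absent from a list are imputed the worst rank 1, the standard
convention for partial lists. RRA consumes each dataset's genes ranked by
permutation score, which is the quantity the upstream stage actually
orders by. Union/intersect order the output by the best per-dataset score
so that downstream trimming is deterministic.

# Background SNR refinement

Signal and background datasets are typically normalized separately; joint
renormalization is expensive and often impossible. The filter therefore
works on *within-sample relative expression*: for each sample, a normal
distribution is fitted by maximum likelihood (mean, divide-by-n SD) to the
log-expression across genes — the working null that most genes are not
differential within a sample — and each value is replaced by its Gaussian
CDF percentile. Any per-sample affine change of the log scale is absorbed
by (μ, σ), so percentiles are comparable across datasets by construction;
this invariance is tested to 1e-10.

For each gene the per-gene normal fit across signal-sample percentiles has
median x̂_S equal to its mean (F⁻¹(0.5 | μ, σ²) = μ), likewise x̂_B for the
background, giving

```
snr = (x̂_S − x̂_B) / σ_B
```

which is exactly (mean difference)/(background SD) of the percentile
vectors — a Cohen's-d-style effect size, and the identity the tests assert
to machine precision. Two-stage reading (fit percentiles, not raw
log-expression) is used throughout: fitting raw log-expression would break
the cross-dataset comparability that motivates the transform.

Edge cases: a constant background percentile vector (σ_B = 0) leaves the
SNR undefined — the gene is kept only if its signal median exceeds the
background median, with a warning; signature genes absent from the
background data cannot be assessed and are kept, with a warning; a single
signal sample degenerates the fit to a point and warns. Counts are
converted to log2-CPM (0.5 prior count) before the transform, matching the
DE route's expression scale.

The SNR threshold defaults to 1 — one background standard deviation of
separation, the conventional "large" effect on this scale — and is
exposed as `snr_threshold`.

# The synthetic data generator

`generate_counts()` draws negative-binomial counts (default dispersion
0.1, typical of bulk RNA-seq) with log-normal base means (meanlog 4,
sdlog 1.2, giving medians near 55 counts), plants a disjoint block of
markers per group multiplied by `2^lfc` in their own group, and optionally
multiplies per-batch log-normal noise. `generate_background()` reuses the
same base means and makes a chosen fraction of each group's markers
background-high while suppressing the rest, so the SNR filter has an exact
truth to be scored against.

The generator emulates: planted group-specific effects, overdispersed
counts, depth variation, batch wobble, background overlap. It does not
emulate: correlated gene modules, composition effects large enough to
stress TMM's trim bounds, outlier samples, or dropout-like zero inflation.
Tests passing on this generator therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to every
pathology of real data.

Test and acceptance problem sizes — 2000 genes, 4 groups × 5 samples, 50
markers, K = 1000, five seeds — were chosen as the smallest configuration
at which the asymptotics the method relies on (rank uniformity,
mean-variance trend estimation) are visibly stable.

# Known limitations

* No random-effect or duplicate-correlation modeling; batch is a fixed
  effect only, and a batch perfectly confounded with a group is an error.
* The permutation null assumes exchangeability of ranks across genes
  within a comparison; strong inter-gene correlation makes scores
  conservative or anticonservative in ways the uniform-null tests do not
  probe.
* RRA aggregation treats dataset lists as uncorrelated, which is
  optimistic when datasets share samples or platforms.
* The SNR working model (within-sample normality of log-expression) is a
  convenience; heavy-tailed samples shift percentiles toward 0.5 and make
  the filter more permissive.
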