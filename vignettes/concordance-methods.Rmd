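---
title: "Methods: cross-species sex-concordance analysis and clonogenic frequency estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species sex-concordance analysis and clonogenic frequency estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexconcord)
```

## The scientific question

Male and female cells differ in their susceptibility to malignant
transformation, and tumour models built from sex-separated cells show
transcriptome-wide expression differences between the sexes. The central
statistical question this package addresses is: *when a set of
sex-differential genes is identified in a mouse tumour model, do the same
genes move in the same female-versus-male direction in human tumour
expression data — more often than random gene sets would?*

The package implements that question as a pipeline of four stages, each
usable on its own:

1. **Differential expression** (`tmm_factors()`, `log_cpm()`,
   `sex_de_test()`, `select_de()`): per-gene sex contrasts on normalized
   count data, with FDR and fold-change selection.
2. **Concordance** (`sex_direction()`, `concordance_fraction()`,
   `resample_null()`, `tail_probability()`, `run_concordance()`): the
   fraction of selected ortholog pairs with matching
   female-minus-male signs, calibrated against a resampling null.
3. **Over-representation** (`hypergeometric_ora()`): hypergeometric
   enrichment of the concordant genes in user-supplied GMT gene sets.
4. **Limiting dilution** (`fit_frequency()`, `compare_frequencies()`):
   single-hit Poisson estimation of clonogenic cell frequency from
   sphere-formation assays, with a likelihood-ratio group comparison.

A negative-binomial simulator with planted ground truth
(`sim_config()`, `generate_paired_expression()`, `generate_ld_assay()`)
makes every stage testable end to end without access to any real data
set.

## The concordance statistic and its null

For each gene the *direction* of the sex effect is the sign of
mean(F) − mean(M) on the log-CPM scale. Given a mouse direction map, a
human direction map and a one-to-one orthology pairing, the observed
statistic is

$$\hat c \;=\; \frac{\#\{\text{pairs with equal sign}\}}
                 {\#\{\text{pairs with a defined sign on both sides}\}}$$

computed over the mouse genes that pass the differential-expression
selection. Genes with an exactly zero mean difference or without an
ortholog are excluded and counted.

Whether an observed $\hat c$ is large is decided against a resampling
null: `resample_null()` draws `n_resamples` sets of `set_size` distinct
genes uniformly without replacement from a *universe* of genes and
records each set's concordance fraction. A normal distribution is fitted
to the null values by moments (the maximum-likelihood fit for a normal),
and `tail_probability()` reports both the upper-tail normal probability
of the observed fraction and the add-one-corrected empirical exceedance
$(1 + \#\{\text{null} \ge \hat c\})/(n_{\text{resamples}} + 1)$, which can
never be exactly zero. The question is directional (is concordance
*enriched*?), so both probabilities are one-sided.

Design choices that were genuinely open:

* **The resampling universe.** `run_concordance()` defaults to drawing
  null sets from *all* expressed, ortholog-mapped genes with defined
  directions (`universe = "all"`). Restricting the universe to the
  significant genes themselves (`universe = "de"`, also implemented)
  makes the null match the observed set by construction and can only
  answer a much weaker question; with `universe = "all"` the null
  measures how concordant *random* gene sets look, which is the
  "by chance" base rate the analysis needs.
* **Set size.** The classic choice is a fixed 500-gene set
  (`resample_null()`'s default). `run_concordance()` instead defaults to
  `set_size = NULL`, meaning "match the observed set size": the null then
  has exactly the sampling variance of the observed statistic, which is
  what makes the empirical p-value uniform under the null. A fixed size
  can always be passed explicitly.
* **Human-side selection.** The human direction is the sign of the mean
  difference with no significance filter. Requiring human-side
  significance would conflate the concordance question with human power;
  sign-only is the weakest assumption and the default.
* **Moments versus histogram.** The normal fit is a convenient smooth
  summary, accurate in the bulk of the null (the package tests agreement
  with the empirical tail within ±2σ); far outside the bulk the normal
  tail is an extrapolation, which is why the empirical probability is
  always reported alongside it.

## The differential-expression stage

The stage is a self-contained, documented equivalent of the standard
count pipeline, built to be auditable rather than to match any external
implementation bit for bit.

**Filtering.** Genes with zero counts in every sample are removed
(`filter_unexpressed()`); a single read in a single sample keeps a gene.

**TMM-style normalization** (`tmm_factors()`). Per-sample scale factors
are computed from trimmed, precision-weighted mean log2 ratios
(M-values) of relative abundances against a reference sample — the
sample whose upper-quartile/library-size ratio is closest to the mean of
those ratios. Genes with a zero count in either sample are excluded
pairwise; 30% of each M tail and 5% of each A tail are trimmed; factors
are rescaled to geometric mean 1. One deliberate difference from the
textbook formulation: the precision weights are computed from relative
abundances rather than raw counts, so the factors depend only on sample
*proportions* and are exactly invariant to rescaling any sample's
counts. On generic data the factors agree with `edgeR::calcNormFactors`
to within ~0.01; the exact-invariance property is what the log-CPM
transform below relies on.

**log-CPM** (`log_cpm()`). Entries are
`log2((count + prior) / (lib * factor + 2 * prior) * 1e6)` with the
prior count scaled in proportion to the effective library relative to
one million. At a one-million library the prior is `prior_count`
(default 0.5) verbatim; the scaling makes the transform exactly
depth-invariant, which a fixed prior is not.

**Moderated t** (`sex_de_test()`). Per gene, the pooled two-group
variance $s^2_g$ (d = nF + nM − 2 df) is shrunk toward the across-gene
mean variance $\bar{s}^2$ with a fixed prior of `d0` degrees of freedom,

$$\tilde s^2_g = \frac{d_0\,\bar s^2 + d\,s^2_g}{d_0 + d},$$

and $t_g = \widehat{\text{log2FC}}_g / \sqrt{\tilde s^2_g (1/n_F + 1/n_M)}$
is referred to a t distribution with $d_0 + d$ degrees of freedom. The
default `d0 = 4` applies mild shrinkage appropriate for small designs
(6–8 samples per sex); `d0 = 0` recovers the ordinary pooled t test
exactly, which the test suite verifies. This is simpler than empirical-
Bayes pipelines that *estimate* the prior df and fit a mean–variance
trend; under the simulator's shared-dispersion count model the p-values
are uniform under the null (Kolmogorov–Smirnov checked across 100 seeded
runs) and the BH selection controls the false-discovery proportion. On
real data with strong mean–variance trends a trend-aware pipeline may be
preferable; the moderated t here is the documented, testable core.

**Selection** (`select_de()`): q ≤ 0.05 (inclusive — a gene at exactly
0.05 is kept) and fold change ≥ 2 (|log2FC| ≥ 1), both configurable. The
fold-change filter matters beyond cosmetics: it is what separates the
strongly sex-differential genes from the small-shift background genes in
the planted simulations.

## What the simulator emulates

`generate_paired_expression()` draws negative-binomial counts
(`variance = mu + dispersion * mu^2`, dispersion shared across genes,
default 0.05) with per-gene baseline means log-uniform over
`exp([log 50, log 5000])` — a realistic dynamic range for moderately
sequenced bulk RNA-seq — independently per species.

* A fraction `frac_sex_de` (default 0.25 of 2400 genes, i.e. 600 genes)
  is sex-differential with |log2FC| = `effect_log2fc` (default 1.5); the
  sign is a fair coin, and the female group mean is multiplied by
  `2^(sign * effect)`.
* The human ortholog receives the same effect size with a sign matching
  the mouse sign with probability `concordance_rate` (default 0.49).
* Every other gene carries a *small* sex shift of `background_log2fc`
  (default 0.7) in both species, signs matching with probability
  `background_concordance` (default 0.28). The magnitude is chosen so
  that the direction is reliably recoverable at the default sample sizes
  (the shift is ~3 standard errors of the fold-change estimate) while
  staying well below the 2-fold selection threshold — this is what makes
  the ~28% "chance concordance" base rate survive the full noisy
  pipeline instead of washing out to 50%. A shift planted on only one
  species could not do this: the other species' empirical sign would be
  a fair coin and the match probability would be exactly one half no
  matter what rate was requested. Setting `background_log2fc = 0` gives
  a clean global null (all signs zero).
* Mouse sample size defaults to 8 per sex (a plausible bulk design);
  the human side defaults to 20 per sex, a deliberately scaled-down
  stand-in for a tumour-expression cohort — large enough that human
  directions of background-size shifts are recovered with high
  probability.
* Optional correlation blocks (`corr_block_size`, `corr_rho`) multiply
  block means by a shared per-sample lognormal factor with log-variance
  `rho/(1-rho) * dispersion`, inducing approximately the requested
  within-block correlation of log counts. Optional `frac_unmapped`
  removes genes from the orthology map to exercise the drop rules.

What the simulator does *not* emulate: batch effects, per-gene
dispersion trends, library-composition biases, count outliers,
single-cell structure, and real orthology complexities (many-to-many
families, missing orthologs beyond random dropout). Passing tests
therefore demonstrate internal correctness and calibration of the
statistics under a clean count model — not robustness to every artefact
of real data.

`generate_ld_assay()` draws positive-well counts binomially with
per-well success probability `1 − (1 − f)^dose` — the exact single-hit
probability that a well receives at least one clonogenic cell. The
default design is the 3000/600/120/24/5/1 cells-per-well serial dilution
with 14 wells per dose.

## Single-hit limiting-dilution estimation

A well plated with $d$ cells is positive when at least one of its cells
is clonogenic; under independent cells with per-cell frequency $f$,
$P(\text{positive}) = 1 - e^{-fd}$ (the complementary log-log model with
offset $\log d$). `fit_frequency()` maximizes the exact binomial
log-likelihood in $\theta = \log f$ — a bracketed search on
$[e^{-30}, 1]$ polished by Newton steps, which is robust at boundaries
where IRLS can fail — and reports a 95% Wald interval on $\log f$,
back-transformed and clipped to [0, 1]. A single-dose design has the
closed form $\hat f = -\ln(\text{negative fraction})/d$, which the fit
reproduces to 10⁻⁹ and the test suite pins.

Boundary designs are flagged rather than silently reported: with no
positive wells anywhere, $\hat f = 0$ and the upper limit is the exact
zero-count bound $-\ln(0.05)/\sum d_i w_i$; with every well positive,
$\hat f$ sits at the working upper bound of 1 per cell and the lower
limit solves $P(\text{all wells positive} \mid f) = 0.05$.

The Wald-on-log(f) interval was chosen over profile likelihood for
simplicity; at the default design and $f = 1/200$ its empirical coverage
is ~96% over 500 simulated assays (tested), and the point estimate's
median bias is under 2%. Profile intervals are a listed extension, and
results from web ELDA tools will differ slightly in the interval (not
the estimate). `compare_frequencies()` tests equality of two groups'
frequencies with a likelihood-ratio statistic (two free fits versus one
pooled fit) against $\chi^2_1$; its type-I error at the default design
is within Monte-Carlo range of 5% (tested), and boundary fits in either
group set a caveat field because the chi-square reference is then
unreliable.

## Over-representation

`hypergeometric_ora()` is a deliberately generic replacement for
proprietary pathway tools: each user-supplied GMT set is intersected
with the universe (all expressed, tested genes by default — not the
genome, which would inflate every overlap), the overlap with the query
is tested with the one-sided hypergeometric upper tail
$P(X \ge k)$, and q-values are BH across the sets of one collection.
Sets that vanish after intersection are skipped with a warning; the
p-values are exhaustively exact (verified by enumeration for universes
up to 15 genes) and conservative for random queries because of
discreteness.

## Numerical and reproducibility choices

* All generators take explicit integer seeds, run them in a local RNG
  scope, and restore the caller's `.Random.seed`; the same configuration
  reproduces bit-identical matrices and byte-identical fixture files.
* The resampling null uses a single seeded generator with a fixed draw
  order (one `sample.int` per resample), so permuting the universe
  changes individual draws but not the distribution.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` and is
  property-tested against the brute-force step-up definition on every
  permutation of up to six p-values.
* Ties in the TMM trimming are handled by midrank (`rank()` defaults);
  a sample whose M-values are all below 10⁻⁶ in magnitude gets factor 1
  outright.
* Degenerate inputs error early with the offending field named:
  all-zero matrices, a sex with fewer than two samples, a resampling
  universe smaller than the set size, frequencies outside [0, 1].

## Problem sizes used in the test suite

The packaged tests and the acceptance script regenerate everything from
code at sizes chosen to exercise the asymptotics that matter while
staying comfortably interactive: 2400-gene, 16 + 40-sample paired
bundles for the end-to-end runs (100 seeded replicates per scenario,
2000 resamples each), 10,000–100,000 resamples for the null-moment and
tail checks, 500 simulated assays for the coverage study and 1000 pairs
for the comparison's type-I error. The headline run in
`analysis/03_concordance.R` uses the full 100,000 resamples.

## Known limitations

* The moderated t uses a single pooled prior variance rather than a
  fitted mean–variance trend; with strong trends (very low counts) its
  calibration degrades before a trend-aware method's would.
* The normal tail probability far outside the null's bulk is an
  extrapolation; treat `p_normal` magnitudes below the empirical
  resolution as order-of-magnitude statements and report `p_empirical`
  alongside.
* The orthology map is one-to-one by construction; genuinely
  many-to-many families must be resolved upstream.
* The single-hit model assumes independent cells and no frequency
  heterogeneity between wells; goodness-of-fit testing of that
  assumption is out of scope.
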