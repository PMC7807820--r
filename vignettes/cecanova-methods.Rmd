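---
title: "Methods: permutation ANOVA and sparse PLS-DA for rabbit cecal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation ANOVA and sparse PLS-DA for rabbit cecal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecanova)
```

## The problem

Growing meat rabbits raised under different management — two breeding farms,
production batches, feed with or without antibiotics, ad libitum (AL) versus
restricted (R) feeding — show differences in cecal microbial composition.
`cecanova` implements the downstream statistics for such a study, starting
from a 16S OTU count table, a sample-metadata table and a taxonomy map:
count filtering, cumulative sum scaling (CSS) normalization, rarefaction,
alpha-diversity contrasts, per-taxon permutation analysis of variance with
false discovery rate control, taxonomy collapse, and sparse partial least
squares discriminant analysis (sPLS-DA) of samples on the management
factors.

The experimental design is unbalanced and nested: 336 of 425 animals come
from farm A (batches 1–4, all on antibiotic-supplemented feed) and 89 from
farm B (batch 5), of which 23 received antibiotic-free feed; feeding regime
is crossed within every farm/batch/antibiotic cell, giving 12 observed
cells (`design_fixture()` packages this layout). Because batch determines
farm, and antibiotic use varies only within farm B, none of the factors can
be analyzed as a free main effect; every comparison must be expressed as a
contrast over the observed cells.

## The cell-means model and its contrasts

All group comparisons use a one-way ordinary least squares fit on the
*combined factor* whose levels are the observed cells of
farm × batch × antibiotic × feeding (`combined_factor()`,
`fit_cell_means()`). Cell means are within-cell sample means; the residual
mean square is the pooled within-cell variance. A comparison is a zero-sum
weighting $w$ of cell means, and a 1-df contrast is tested with

$$F = \frac{\left(\sum_g w_g \bar y_g\right)^2}
           {\widehat{\sigma}^2 \sum_g w_g^2 / n_g},$$

the square of the pooled $t$ statistic. `standard_contrasts()` builds the
reported family with *unweighted* averages over cells (a Type-III-like
convention, appropriate because batches are unbalanced): farm (mean of the
8 farm-A cells minus mean of the 4 farm-B cells), feeding within each farm
and averaged over farms (R minus AL), and antibiotic within farm B (without
minus with).

A feeding-by-farm interaction contrast (difference of the within-farm
feeding effects) decides presentation: when it is significant at the
working threshold the feeding comparison is reported nested within farms,
otherwise averaged over them. `run_differential_abundance()` applies this
rule per taxon and marks the rows accordingly (`reported` column).

## Permutation inference

OTU counts are far from Gaussian, so per-taxon p-values do not rely on the
theoretical F distribution. Instead the response is permuted globally over
samples (without replacement, the design matrix held fixed), the contrast F
is recomputed each round, and the empirical p-value is the proportion of
rounds with $F^* \ge F_{\mathrm{obs}}$, ties counting as exceedances. The
default is 1000 permutations, giving a p-value resolution of 0.001.

Two numerical details matter:

* **Zero p-values and FDR control.** Under the plain counting definition
  the smallest achievable p-value is 0 (probability $1/(n_{perm}+1)$ under
  the null), and a p-value of exactly 0 survives any step-up procedure, so
  Benjamini–Hochberg control degrades at the bottom of the scale. The
  add-one estimator $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$ is available via
  `add_one = TRUE` (and as a monotone transform of the returned p-values);
  it is positively biased but never zero, and it is what the package's own
  null simulations use when checking the post-BH false discovery
  proportion. The counting definition remains the default because it is
  the conventional printed form.
* **Permutation streams.** One master seed drives everything; each taxon's
  permutation stream is keyed by a hash of (master seed, taxon name), so
  results do not depend on the order in which taxa are processed, and a
  `share_permutations` flag reuses a single stream across taxa when speed
  matters more than stream independence. Whether permutations should be
  redrawn per taxon is not identifiable from the analysis description we
  follow; per-taxon streams are the default.

P-values are BH-adjusted *within one contrast across all tested taxa*,
separately per contrast and per taxonomic level, matching per-table
reporting of adjusted values; the family for the two alpha-diversity
indices is the set of reported contrasts per index (the printed adjusted
values do not define their family, so this is a documented convention).

Alpha diversity (observed OTUs and the natural-log Shannon index, computed
on the table rarefied to 10,000 reads) uses classical theoretical-null F
tests on the same cell-means model: the indices are approximately Gaussian
aggregates, and the permutation machinery is reserved for composition.

## Filtering, CSS and rarefaction

Filtering follows the stated rules exactly: samples with fewer than 5000
total reads are dropped (strict inequality); OTUs with total count at most
2 are dropped (`remove_doubletons()` removes singletons too — open-reference
pipelines rarely retain informative singletons; the threshold is an
argument); and before per-OTU testing an OTU must be detected in at least
5% of samples (inclusive, on the ceiling) *and* have a total count strictly
greater than 0.01% of the grand total.

CSS normalization divides each sample's counts by $s_j$, the cumulative sum
of its counts up to a quantile of its *nonzero* count distribution, times a
scale constant (default 1000). When no quantile is supplied it is chosen by
the instability criterion of the cited method: scanning quantile levels,
the chosen level is the first at which the median absolute deviation of
per-sample quantiles around the across-sample reference changes by at least
10% relative to the next level, floored at 0.5 (and falling back to 0.5
with a warning if the criterion is never met). Zeros map to zeros, and
normalized values are invariant to multiplying a sample by a constant.

Rarefaction subsamples each retained sample *without replacement*
(multivariate hypergeometric, delegated to `vegan::rrarefy`) to exactly the
target depth, default 10,000; under-depth samples are dropped with a
message rather than an error, mirroring standard practice (in the emulated
study the minimum library, 10,157, exceeds the depth, so nothing is
dropped). Taxonomy collapse operates on the CSS-normalized table (the
convention of the relative-abundance tables this mirrors), pools OTUs
unassigned at the rank into an `unclassified` bucket, and rescales each
sample to percentages.

Average daily gain is the within-animal OLS slope of weekly body weight on
age in days (g/day).

## Sparse PLS-DA

`splsda()` is implemented from first principles in the regression-mode
discriminant form. Classes are dummy coded; X is centered and
unit-variance scaled (a flag disables scaling; Y is always standardized).
Per component the leading singular-vector pair of the deflated
cross-covariance $X^\top Y$ is found by alternating iteration, with the
X-loading soft-thresholded at the $(keepX+1)$-th largest magnitude and
renormalized, so each component carries exactly `keepX` variables (ties at
the threshold are broken by feature order, deterministically). X and Y are
deflated by regression on the component score. Prediction standardizes new
samples with the training parameters, projects them through the training
loadings with the same deflation, and assigns the nearest class centroid in
score space (Euclidean distance; exact ties go to the lexicographically
smallest label). With `keepX = p` the first loading equals the leading
right singular vector of $Y^\top X$, which the test suite verifies against
a direct singular value decomposition, and the full fit is cross-checked
against the mixOmics reference implementation on a small instance.

Tuning (`tune_splsda()`) is forward per component on a keepX grid, scoring
each candidate by mean balanced error rate (BER — the unweighted mean of
per-class error rates) over repeated stratified 5-fold cross-validation
(default 10 repeats, at most 4 components); ties prefer the smallest keepX
and components are added only while the mean BER improves. Performance
assessment (`evaluate_splsda()`) repeats stratified 5-fold cross-validation
with fresh partitions (so 20% of each class is held out in every fold),
reporting mean and standard deviation of overall and per-class BER plus the
*stability* of every variable — its selection frequency across all fold
fits — flagging variables above 0.9. The keepX grid is not dictated by the
analysis we emulate; `c(1, 5, 10, 25, 50, 70)` is the package default.
Tuning minimizes plain mean BER, with no one-sided significance rule on
component addition.

## The synthetic generator

`generate_counts()` produces tables with the statistical structure the
analysis assumes, with known ground truth:

* **Design**: any validated metadata table; the default is the 425-animal,
  12-cell fixture.
* **Library sizes**: log-normal (default meanlog $\log 20000$, sdlog 1)
  truncated below at 10,157 by resampling — reproducing the scale of the
  emulated data (mean ≈ 35,000, long right tail).
* **Composition**: a log-normal base abundance over OTUs (default sdlog 2,
  heavy-tailed, so a few OTUs dominate and many are rare), or an explicit
  base composition.
* **Effects**: multiplicative $2^{lfc}$ factors on expected relative
  abundance for chosen (OTU, factor) pairs, applied to the factor's
  first-named level before renormalization — so planted effects are
  compositional, and strong planted effects necessarily perturb the
  relative abundances of unaffected OTUs (renormalization spillover), just
  as real compositional effects would.
* **Counts**: Dirichlet-multinomial per sample, concentration 200 by
  default — moderate overdispersion chosen so that prevalence patterns
  (a core of OTUs present in every sample, a long tail of sporadic ones)
  resemble the emulated tables; as the concentration grows the generator
  converges to multinomial sampling, which the test suite checks by a
  variance-ratio test.

`generate_taxonomy()` assigns every OTU a phylum and most a genus (15%
genus-unassigned by default), nested consistently, with 8 phyla and 28
genera by default. `generate_weights()` adds weekly body weights on a
linear growth model at ages 32–60 days.

What the generator does *not* emulate: phylogenetic correlation between
OTUs, batch-level technical effects, zero-inflation beyond what the
Dirichlet-multinomial induces, age drift within the fattening period, and
cage or litter structure. Passing tests therefore demonstrate correctness
of the statistical machinery under a plausible compositional model, not
robustness to every feature of real sequencing data.

## Validation conditions and problem sizes

The package validates itself on simulations whose conditions are fixed
once:

* **Classifier analog**: two farms, 60 samples each, 400 OTUs, 10 OTUs
  planted with 8-fold shifts in expected relative abundance placed on OTUs
  with base relative abundance above 0.2% (a shift can only separate
  classes if the OTU carrying it is quantifiable at the realized sequencing
  depth); tuning by 5-fold × 10 and evaluation by 5-fold × 50
  cross-validation. The tuned model classifies perfectly (BER 0.00),
  reproducing the pattern of the farm classifier this emulates.
  `scripts/acceptance.R` recomputes exactly this quantity.
* **Size**: 200 null tables (425 samples × 200 OTUs, 200 permutations):
  per-contrast type-I error within 0.05 ± 0.02, and post-BH false
  discovery proportion (add-one p-values) at most ~0.05.
* **Power**: 50 of 400 OTUs planted with farm effects of $|lfc| \in
  [1.5, 2.5]$ on OTUs above base relative abundance $5 \times 10^{-4}$
  (effects planted below the study's own abundance filter are removed
  before testing and are unrecoverable by construction): sensitivity at
  least 0.8 at FDR 0.05 and rank correlation above 0.9 between estimates
  and true expected-abundance differences.
* **Diversity recovery**: a planted 40-unit farm shift in observed OTUs on
  the full design (residual SD 75, chosen to reproduce the ~9.8 standard
  error of the contrast) is recovered within one standard error, averaged
  over 25 replicates. The shift is planted directly on the per-sample
  index: the cell-means contrast machinery is what is under test, and no
  closed-form control links generator parameters to a richness difference.

Evaluation repeats are reduced to 50 in these checks (the reference
protocol's 1000 remains the default of `evaluate_splsda()` and of the
pipeline configuration); 5 CSS oracle matrices, exhaustive BH enumeration
to length 8 over a 3-point grid, and 1000-seed rarefaction means complete
the oracle suite.

## Degenerate inputs and edge rules

Constant responses give F = 0 and permutation p = 1. A contrast touching
an unobserved cell, a sample of all zeros under CSS, metadata that fails
the design invariants (batch 1–4 must be farm A, batch 5 farm B, farm A
implies antibiotics), non-hierarchical taxonomy, and misaligned
sample/metadata identifiers all error early with specific messages.
Zero-variance features are dropped (with a warning outside cross-validation
loops) before sPLS-DA. Rarefaction of a sample exactly at depth returns it
unchanged.

## Known limitations

The permutation test permutes globally rather than within strata, matching
the description it follows; stratified permutation would give exactness
under within-farm exchangeability but is deliberately not the default.
Standard errors in the contrast tables are OLS standard errors, not
bootstrap ones. No litter, cage or other random effects are modeled. BER
confidence from repeated cross-validation understates variability because
repeats share the data. The pipeline's sPLS-DA stage classifies on a
single configured factor per run.
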