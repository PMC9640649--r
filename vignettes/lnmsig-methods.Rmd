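---
title: "Methods and design of the lnmsig pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the lnmsig pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmsig)
```

`lnmsig` implements the computational backbone of a multisite proteomics
study of lymph-node metastasis: discovery-phase LFQ analysis, clustering
and clinical association, EMT scoring of matched tumor/node pairs,
targeted-assay quantification with its quality gates, and an exhaustive
machine-learning search for small diagnostic signatures. This vignette
describes each model, the assumptions behind it, the tunable parameters,
and the design decisions taken where the procedure was genuinely open.

## 1. Missingness and imputation

LFQ intensities are analysed on the log2 scale. Missing values in such
data are predominantly *missing not at random* (MNAR): a protein near the
instrument's detection limit drops out preferentially, so the missing
mass sits in the left tail of each sample's intensity distribution.

`impute_downshifted()` adopts the standard down-shifted-normal model:
for sample column $j$ with observed mean $\mu_j$ and sample (n−1)
standard deviation $\sigma_j$, each missing cell is drawn independently
from

$$x \sim N(\mu_j - \text{shift}\cdot\sigma_j,\; (\text{width}\cdot\sigma_j)^2),
\qquad \text{shift} = 1.8,\ \text{width} = 0.3 .$$

Both defaults are dimensionless multiples of the per-sample SD, in
keeping with the Perseus convention. Assumptions worth stating: the
imputation is *per sample column* (the orientation is features × samples,
so "column statistics" are sample statistics); $\sigma$ is the $n-1$
sample SD; and a column must hold at least two observed values or the
function stops naming the offending sample. Draws are re-seeded per
column from `(seed, sample_id)`, so adding or dropping a column never
perturbs the draws of the others — a reproducibility property the test
suite asserts.

Imputed tables are used for clustering and PCA only. Differential testing
runs on the *un-imputed* table, because the exclusivity rule
(section 2) is a statement about the detection mask and would be
destroyed by filling the holes.

## 2. Differential abundance and exclusivity

Per feature, groups pN+ vs pN0 are compared with a two-sided
equal-variance (pooled) Student *t*-test — not Welch, matching the
upstream software the procedure mirrors — provided each group has at
least `min_obs_per_group = 2` observed values (the minimum is a declared
choice; two observations are the least that define a variance). The
"Ratio" is the difference of log2 group means, i.e. the log2 of the
geometric-mean intensity ratio. Features with zero pooled variance are
routed to the not-tested path rather than reported as spuriously
significant.

A feature *detected exclusively in one group* is differential by
detection. Two variants exist in the pipeline, mirroring the two
analysis levels:

* at the p-level (`use_fdr = FALSE`), any exclusive detection qualifies;
* at the FDR level (`use_fdr = TRUE`), the feature must additionally be
  detected in at least `exclusive_min_fraction = 0.5` of the detecting
  group's samples — the "at least 50% of samples" volcano rule.

Benjamini–Hochberg correction is computed over tested features only;
exclusive features never enter the BH pool (they carry no p-value).

## 3. Clustering grid and clinical association

`linkage_grid()` evaluates hierarchical clustering over three linkage
methods (complete, weighted/WPGMA, Ward) crossed with 22 distance
metrics, with per-cell failure isolation: a singular covariance under
`mahalanobis`, or negative inputs under `jensenshannon`, annotate that
cell without aborting the grid. Ten of the metrics (dice, jaccard,
hamming, matching, kulsinski, rogerstanimoto, russellrao, sokalmichener,
sokalsneath, yule) are set/binary measures; applying them to continuous
log2 intensities is mathematically dubious, so by default they operate
on the *detection mask* (observed = 1), which is also the biologically
meaningful reading — they then cluster samples by shared detection
patterns. A compatibility flag (`binary_on_values = TRUE`) reproduces the
generic-library behavior of feeding them raw values. Similarly, Ward
linkage is only defined over Euclidean-family distances; non-Euclidean
Ward cells are marked unsupported by default and can be forced with
`ward_strict = FALSE` (the permissive behavior of the generic stacks
that produced "Ward + Chebyshev"-style selections).

Metric definitions follow SciPy's, and the test suite pins them to a
frozen SciPy reference on a fixture; `kulsinski` and `sokalmichener`,
retired from current SciPy, use the historical closed forms (the latter
is numerically identical to rogerstanimoto, which is why it was
retired).

Flat 2-group cuts label the larger cluster `C1` (ties broken by first
sample in input order; the naming is a convention, nothing downstream
depends on it). `associate_clusters()` tests each categorical covariate
against the cut with the two-sided Fisher exact test; multi-level
covariates are dichotomized against their modal level (r×c exact tests
are out of scope — reported associations are 2-cluster × binary), and
constant covariates are skipped with a note. Zero-margin tables are
degenerate and reported as p = 1 with a flag.

## 4. EMT scoring of matched pairs

Given a signature labelling proteins epithelial (`Epi`) or mesenchymal
(`Mes`), the per-sample score is

$$\text{EMT} = \overline{x}_{\text{Mes,observed}} -
               \overline{x}_{\text{Epi,observed}},$$

higher = more mesenchymal. Missing proteins are ignored per sample, and a
sample with fewer than `min_per_class = 3` observed proteins in either
class is flagged invalid rather than scored from near-empty overlap
(a guard the source procedure does not specify; three is the smallest
count for which a mean is at all stable). The package ships only a
synthetic 10-gene toy signature; published signatures (such as 76-gene
EMT panels) are supplied by the user as a two-column TSV, since the
package does not embed third-party gene lists.

Matched tumor/node scores are compared with the normality-guided paired
test: Shapiro–Wilk on the *paired differences* (that is the quantity
whose normality the paired *t* assumes) at α = 0.05 selects the paired
Student *t* or the two-sided Wilcoxon signed-rank test (zeros dropped).
One boundary case is worth recording: an exactly constant shift has
zero-variance differences, on which the Shapiro–Wilk statistic is
undefined; such data are routed to the signed-rank branch, whose exact
p-value floor at $n$ pairs is $2/2^{n}$.

## 5. The signature × classifier search

The search space is every variable subset of size 1 to `max_size = 5`
(the binomial-sum $\sum_k \binom{V}{k}$; enumeration is deterministic —
by size, then lexicographic — and streamable so the 45-variable space of
1,385,979 signatures never needs materializing), crossed with ten
classifier families. Missing panel values are replaced with 0 before
modelling, per the reference preprocessing for targeted-panel data.

**Cross-validation.** Each pair is evaluated by R = 10 repetitions of
stratified K-fold CV with K = the smallest class size, for exactly
R·K trained models per pair. With that K, each fold holds a single
minority-class sample, so a per-fold AUC is ill-defined; the package
therefore pools the out-of-fold continuous scores of each repetition
into one ROC AUC, giving R AUC values per pair (a per-fold mode exists
behind a flag for larger folds). Fold partitions are generated once per
repetition from the base seed and shared across all pairs, so AUC
distributions are comparable between pairs. Sensitivity, specificity and
precision come from pooled hard predictions at each family's native
decision threshold (score > 0), since no threshold is prescribed.

**Selection.** The pair with the highest mean AUC is *top-1*; ties break
to the smaller signature, then lexicographically, then by the canonical
family order — an invented but documented rule. Every other pair's R AUC
values are compared to the top-1's with a two-sided equal-variance
*t*-test, and pairs that cannot be distinguished (p ≥ 0.05) are
*selected*. Two identical constant AUC vectors are equivalent by
definition (p = 1); if only one vector is constant the test falls back
to exact equality of means.

**Permutation validation.** The permutation test re-runs the entire CV
on label-shuffled data (folds re-stratified per permutation) and reports
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so
p = 0 is impossible and the floor with the default 100 (or the
conventional 99) permutations is 1/101 (1/100). High-performance
candidates are the selected pairs with mean AUC ≥ 0.85 *and* permutation
p ≤ 0.05, both bounds inclusive. Marker frequency is the percentage of
distinct high-performance signatures containing each variable.

**Classifier engine.** The pre-installed R stack provides none of the
usual classifier packages (no rpart/e1071/randomForest), so the ten
families are implemented in compiled code (RcppArmadillo) with fixed,
recorded hyperparameters: ridge regression on ±1 labels (λ = 1, the
closed form), lasso by coordinate descent (λ = 0.05), linear SVM by
deterministic full-batch subgradient descent on the L2-regularized hinge
(λ = 0.01, 200 epochs), pooled-covariance LDA with a tiny ridge jitter,
a deterministic averaged perceptron (100 cyclic epochs), Gaussian naive
Bayes with a variance floor, greedy Gini CART (depth 3), gradient
boosting with logistic loss over depth-2 regression trees (100 stages,
shrinkage 0.1, Newton leaf values), a 100-tree random forest (bootstrap
+ √p feature subsampling, seeded Mersenne Twister), and an RBF
least-squares SVM (LS-SVM, C = 1, γ = 1/(V·var), the kernel
regularized least-squares form of the SVM family). All families except
the forest are fully deterministic; the forest is deterministic given
the seed. The linear families are unit-tested against independent
references (the ridge closed form recomputed in R, MASS::lda
posteriors). Compilation is what keeps full permutation testing of
cross-validated AUCs — millions of model fits — inside a desk-scale CPU
budget.

No feature scaling is applied by default (the reference preprocessing
states only zero-substitution); within-fold standardization is available
via `classifier_spec(..., standardize = TRUE)` for scale-sensitive
families.

## 6. Targeted-assay quantification and QC

Peptide intensity is the sum of transition areas; quantity is the
light/heavy ratio. Spectral agreement uses the normalized dot product
(cosine). The exact intensity transform under the published dotp/rdotp
gates is not specified anywhere in the source procedure; the package
defaults to square-root-transformed intensities — the dominant
targeted-proteomics convention for library dot products — with
`sqrt_transform = FALSE` available. The gates themselves are faithful to
the published wording: rdotp ≥ 0.9 include, rdotp ≤ 0.8 exclude
(inclusive), manual review between; dotp strictly > 0.7; mass error
strictly < 10 ppm. Carryover is 100 × blank area / preceding-run area on
summed transition areas (apex-vs-sum is unstated; summing matches the
intensity definition used for quantification).

For qPCR, amplification efficiency is $E = 10^{-1/\text{slope}} - 1$
with the inclusive 95–105% acceptance band; non-detects are imputed at
the maximum cycle number Cq = 40; and relative quantification follows
the Pfaffl model
$\text{ratio} = (1+E_t)^{\Delta Cq_t} / (1+E_r)^{\Delta Cq_r}$ with
$\Delta Cq$ = calibrator − sample. With several reference genes (the
blood analyses use two) the reference term is the geometric mean of the
per-reference terms — the natural multi-reference generalization, on
which the source is silent. With all efficiencies at 1 the model reduces
exactly to the Livak $2^{\Delta\Delta Cq}$, a property the tests check
across random grids.

## 7. The synthetic-data generators: what they do and do not establish

The generators produce every input the pipeline consumes, with recorded
ground truth:

* `generate_group_quant()` — log2 LFQ-like matrices: feature baselines
  N(25, 2²) with within-feature noise N(0, 1²) (typical LFQ log2
  ranges), and a planted subset carrying an additive group shift.
* `apply_mnar_missingness()` — cellwise MNAR: the missingness
  probability is a decreasing logistic in the cell's pre-missingness
  value, with the midpoint calibrated by bisection so the expected
  missing fraction hits the target (±0.02 realized). The steepness
  defaults to 1 per log2 unit.
* `generate_marker_panel()` — multi-layer (peptide/protein/transcript)
  panels in which all layers of a marker load on one standard-normal
  latent factor; loadings are chosen so any two layers of a marker
  correlate at exactly ρ, and informative markers separate the groups by
  `effect_size` latent-SDs.
* `generate_paired_sites()` — matched tumor/node columns with Mes
  proteins shifted up in tumor and Epi proteins up in node, so the
  expected paired EMT-score difference is 2 × shift.
* `generate_transition_runs()` — Skyline-like transition reports where
  the light channel is the heavy pattern × ratio × log-normal
  distortion, plus optional blank injections with a controlled residual.

What these emulate: left-censoring, planted effect sizes, correlated
molecular layers, paired sampling, transition-level structure. What they
do *not* emulate: inter-sample normalization artifacts, batch effects,
correlated features beyond the marker latent, peptide chemistry,
chromatographic peak shape, or realistic protein-abundance tails. A
green recovery test therefore establishes that the pipeline's inference
machinery is correct under its own assumptions — not that those
assumptions hold in any particular cohort.

Generator defaults are part of the stated world of the acceptance tests
and are not tuned against outcomes. One interpretation choice: the
"15-marker panel" of the recovery criterion is realized as one protein
variable per marker (15 variables), matching the 15-variable phrasing of
the associated invariants.

## 8. Numerical choices and degenerate inputs

* Seeds: all randomness flows through a 31-bit deterministic hash of
  `(seed, context tokens)`, so every stage is a pure function of its
  config; R's global RNG state is saved and restored around draws.
* Zero-variance t-tests: identical constant groups give t = 0, p = 1;
  unequal constants give a distinct degenerate signal (NA), never p = 0.
* AUC ties contribute 0.5 via average ranks; a constant score yields
  exactly 0.5. Flipping the labels — or the scores — maps AUC to
  1 − AUC; flipping both leaves it invariant.
* The Fisher p-value is the sum of hypergeometric probabilities ≤ the
  observed table's (with a 1 + 1e−7 relative guard in the test oracle
  against floating-point ties at the boundary).
* Stratified folds guarantee both classes in every training set whenever
  K ≤ the smallest class size; the engine still verifies and aborts with
  a named repetition/fold if a class ever vanishes.
* `enumerate_signatures()` refuses to materialize more than 5 × 10⁵
  candidates and points to the streaming iterator instead.

## 9. Known limitations

* The equivalence *t*-test on R = 10 AUC values is low-powered and its
  Gaussian assumption on bounded AUCs is approximate; with very small
  CV spread it is conservative (few equivalents survive), which the
  recovery tests reflect.
* The permutation test treats the CV mean AUC as the statistic;
  permutations re-stratify folds, so permutation variance includes
  partition noise.
* Multi-level covariate association is modal-vs-rest only.
* The decision-tree/GBM/forest implementations are compact CARTs
  sufficient for ≤ dozens of variables, not engineered for large p.
* qPCR support covers efficiency, non-detect imputation and Pfaffl
  ratios; melt-curve or replicate-QC logic is out of scope.
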