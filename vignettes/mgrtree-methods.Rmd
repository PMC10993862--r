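---
title: "Model-based recursive partitioning for multidimensional graded response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based recursive partitioning for multidimensional graded response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-item survey scales are modeled with latent variables: a confirmatory
factor analysis (CFA) model when the responses are treated as continuous, or
a multidimensional graded response (MGR) model when they are ordered
categories. Either way, substantive conclusions require measurement
invariance — the item parameters must not depend on who is answering. When
item parameters do depend on covariates of the respondents, the scale shows
differential item functioning (DIF), and group comparisons on the latent
variables can be artifacts.

The classical tests for DIF require pre-specifying the groups to compare.
`mgrtree` instead searches for DIF subgroups: it recursively partitions the
sample over a set of covariates ("partitioning variables"), testing at every
node whether the fitted measurement model's parameters are unstable with
respect to any covariate, and splitting where the instability is strongest.
A random-split forest extension recovers subgroup structures that no single
tree can represent.

## Models and estimators

**Measurement models.** An `mgr_spec` describes items, latent variables, the
loading pattern with free/fixed entries, and the response scale. The ordinal
model is the probit cumulative model: the probability of responding in
category `k` or above is `pnorm(beta_i' xi - alpha_ik)`, with thresholds
strictly increasing within an item. Its factor-analytic form assumes a
normal latent response `y*` behind each item, cut at the thresholds; the
latent responses carry unit-variance uniqueness, which fixes the scale (no
free residual variances in ordinal specs). The numeric model is the ordinary
CFA with intercepts and residual variances. Identification follows the
anchoring rule: a latent variable's variance is fixed at 1 exactly when its
first loading is free, and free when all its loadings are fixed.

The built-in `pieg_spec()` constructs the probit multistate model with
latent item-effect variables (PIEG) used throughout the simulations: one
reference state latent per time point, one item-effect latent per
non-reference item, all discriminations fixed at 1, all thresholds free, and
a fully free latent covariance matrix. With 3 time points, 3 items each and
5 categories this yields 51 free parameters (36 thresholds, 5 latent
variances, 10 latent covariances); the numeric twin has 33 (9 intercepts, 15
latent (co)variances, 9 residual variances).

**Tree growth: limited-information ML.** `fit_ml()` minimizes the ML
discrepancy `F_ML = ln|Sigma(theta)| + tr(S Sigma^{-1}(theta)) - ln|S| - m`.
During tree growth, ordinal responses are deliberately treated as numeric
scores 0..K-1 and the spec is swapped for its numeric twin: this is a
compromise on the distributional assumptions, made because casewise
log-likelihood contributions — and hence the score matrix driving the
instability tests — are cheap for the multivariate-normal kernel and are not
available for the WLS estimator. Consequences of the compromise are examined
empirically (below). The casewise log-likelihood omits the additive
`-(m/2) ln(2*pi)` constant; it cancels from every difference, score, and
likelihood-ratio statistic the package computes.

Free intercepts are profiled out at the sample means. Variances are
log-transformed and a fully free latent covariance matrix is optimized
through its Cholesky factor with log-transformed diagonal, so positive
definiteness and threshold ordering hold by construction. Convergence is
declared when the casewise score sums satisfy the estimating equations
(`max |sum_j psi_j| <= 1e-5 * n`), or when the transformed-scale gradient
vanishes while the natural-scale score sums do not — the signature of a
boundary optimum with a near-singular latent covariance. Boundary optima are
common in small or contaminated nodes (the data support fewer than five
latent dimensions); they are flagged (`boundary = TRUE`) but kept, because
discarding them would silently prune exactly the heterogeneous nodes the
tree should keep splitting. Score columns are centered before the
fluctuation process is built, which re-anchors the process at zero under
optimizer slack and at boundary solutions.

**Terminal nodes: distribution-free WLS.** Parameter instability tests need
casewise scores and are not available for WLS fits, so WLS is used where
distributional honesty matters and nothing needs to be tested: the terminal
nodes. `polychoric()` estimates thresholds from univariate cumulative
proportions (`qnorm` of the empirical CDF) and pairwise polychoric
correlations by maximizing each 2-way table's bivariate-normal likelihood
with thresholds held fixed (two-step estimation). The bivariate normal CDF
is computed by a Gauss–Legendre implementation of the standard
boundary-transform algorithm (accuracy ~1e-14, verified against an
independent implementation in the test suite). The asymptotic covariance of
the stacked correlations is assembled empirically from casewise
pairwise-likelihood influence contributions (score over information, outer
products across cases); threshold-estimation variability is not propagated,
a standard two-step simplification whose effect on the chi-square
calibration proved negligible in simulation (mean chi-square close to its
degrees of freedom under the true model).

`fit_wls()` minimizes `F_WLS = (kappa_hat - kappa(theta))' W (kappa_hat -
kappa(theta))` over the structural parameters, where `kappa(theta)` is the
model-implied correlation vector of the latent responses (unit-diagonal
normalization; thresholds enter only through step one) and `W` is the
inverse of the empirical asymptotic covariance (full WLS; `weights =
"diagonal"` and `"identity"` are provided as labelled deviations). The test
statistic is `chi2 = n * F_WLS` — the `n` convention, not `n - 1` — with
`df = m(m-1)/2` minus the number of structural parameters. RMSEA is
`sqrt(max(chi2 - df, 0) / (df (n - 1)))`, with a 95% confidence interval by
inverting the noncentral chi-square distribution (the default confidence
level matches common reporting practice). The optimizer takes a
moment-matching start — the implied covariance is linear in the latent
covariance matrix, so an iterated least-squares solve with re-estimated
scalings lands near the optimum — and BFGS with an analytic gradient
finishes; iteration caps keep degenerate leaves cheap at an immaterial cost
in the fourth decimal of `F_WLS`.

## Parameter instability tests

For a fitted node model, the casewise score matrix `psi(y_j, theta_hat)`
(derivatives of the casewise log-likelihood at the optimum; analytic,
validated against central differences) is decorrelated by the root inverse
of its empirical covariance and accumulated along a covariate ordering into
the process `B(j/n)`. Under parameter stability this converges to a
Brownian bridge per component. Three statistics are used:

* **maxLM** (numeric covariates): the maximum of `||B(t)||^2 / (t(1-t))`
  over admissible cuts, trimmed to `t` in `[0.1, 0.9]` by default (the
  conventional trimming; the tree additionally respects its minimum node
  size). Ties in the covariate keep cases adjacent, cut only between
  distinct values, and randomize within-tie order under a stated seed.
* **LMuo** (unordered categorical): the sum over categories of the scaled
  squared category score sums; asymptotically chi-square with `k(C-1)`
  degrees of freedom.
* **maxLMo** (ordered): the maximum of the LM form over the `C-1` level
  cuts at the cumulative proportions.

p values are simulated from the limiting process by default (5000 seeded
replicates; LMuo uses its exact chi-square tail). The maxLM reference
simulates the bridge on a 201-point grid spanning the trimmed interval — a
numerical approximation to the supremum over the continuum whose effect on
calibration is absorbed into the measured rejection rates below. A
closed-form boundary-crossing approximation for maxLM is available
(`method = "closed_form"`); it agrees with simulation to better than 0.01
in the tail (p below roughly 0.05) and overstates moderate p values by up
to ~0.06, so it serves as a tail surrogate, not a default. When an observed
statistic exceeds every simulated replicate, the p value continues with the
closed-form tail (maxLM) or a Bonferroni chi-square tail over the cuts
(maxLMo) capped at the simulation floor `1/(n_sim+1)` — without this,
covariates tested by continuous closed forms would always win selection
against simulated p values under strong DIF, a ranking artifact, not a
statistical judgment.

Scores are taken with respect to the full growth-model parameter vector
(intercepts and residual variances included) by default; `score_params =
"vartheta"` drops those columns to test only the item-parameter block. The
full vector is the default because the growth model estimates those
parameters and their instability is evidence of DIF in the discretized
responses, but the question of which set detects DIF better is left open
and both are exposed.

At each node every candidate covariate is tested, p values are
Bonferroni-multiplied by the number of covariates tested at that node, and
the covariate with the smallest adjusted p value below `alpha = 0.05` is
selected; otherwise the node is a leaf. Measured at the root with eight
covariates on homogeneous data (no DIF, n = 2000), the family-wise
rejection rate sits near the nominal 0.05 (the acceptance script recomputes
it on every run).

## Trees and split-point search

Three split-point strategies are implemented behind one interface
(`mgr_tree_control(method = ...)`):

* `"score"` (default): the boundary at the argmax of the selected
  covariate's score statistic; one model fit per node. For unordered
  categorical covariates, all `2^(C-1) - 1` binary partitions of up to 10
  observed categories are scored by the two-sample LM form; ties break to
  the smallest boundary or lexicographically smallest subset.
* `"objective"`: one fit per admissible segmentation; the boundary
  minimizes the summed minimized negative log-likelihoods of the two
  children. (Minimizing the sum of the children's `F_ML` values is not the
  same criterion: the `ln|S_child|` terms and the child sizes depend on the
  segmentation. The summed-deviance form is the segmented-objective
  comparison the method descends from, and it is the one implemented.)
* `"naive"`: the original exhaustive likelihood-ratio search, selecting by
  the smallest Bonferroni-adjusted LR p value. The maximum is taken over
  all candidate boundaries, and the LR statistic is referred to the
  chi-square with k degrees of freedom without a maximal-selection
  correction; the anticonservativeness this induces — the tree can keep
  splitting on stable nodes — is inherent to the procedure, is the reason
  it is superseded by the score-guided search, and is reproduced as
  documented behavior, not repaired.

Children must each hold at least `min_size` cases (boundary admissibility)
and at least `k + 10` cases for the growth-stage fit, where `k` is the
free-parameter count — an explicit fitting floor distinct from the
user-facing minimum. Terminal nodes of ordinal trees are WLS-refit;
numeric trees store ML fit indices instead (`chi2 = n F_ML` against the
saturated covariance model).

`classify_tree_stability()` scores a tree against a generator manifest at
three levels: `stable` (leaf partition equals the planted partition),
`inaccurate_split_point` (all split covariates relevant and non-numeric
boundaries exact; snapping numeric boundaries to the truth reproduces the
partition), `incorrect_split` (anything else).

## Forests

`mgr_forest()` grows `n_trees` trees on the full sample — no bagging, so
terminal-node estimates are replicable on the original data and fit indices
comparable across trees (a bootstrap flag exists, defaults off, and is
labelled non-canonical). Decorrelation comes from redrawing `mtry` random
candidate covariates at every node. Leaves passing a fit cutoff (RMSEA at
most 0.05 by default, or a chi-square p-value criterion) are pooled;
subgroups are identified by their case-index sets, not rule strings, so
different-but-equivalent rules merge, with `freq` counting the trees that
found each set and strict-subset relations annotated. Per-tree seeds derive
deterministically from the master seed and the simulated-null references
are shared across trees, so a forest is a pure function of (data,
covariates, spec, controls, seed); growth is sequential, which makes the
determinism contract independent of any parallelism degree.

A note on the cutoff: pure-noise responses (uniform categories) have
near-zero polychoric correlations, which the PIEG structure reproduces
exactly at the boundary of its parameter space, so random leaves typically
*pass* an RMSEA cutoff. The filter separates structured-from-misfitting
leaves; it does not certify that a passing leaf is a planted subgroup. What
keeps noise out of the reports in practice is the stopping rule (no
instability, no split), and what identifies the real subgroups is their
recurrence across trees and their non-subset position in the fit-sorted
report — the reason the report annotates subset relations.

`recovery_experiment()` repeats the scenario-2 pipeline over independent
datasets and scores recovery. A planted subgroup counts as recovered when
some report's case set equals it exactly; a Jaccard-similarity relaxation
(default 0.95) is computed separately when requested, since exact case-set
equality is the strictest reasonable operationalization.

## The synthetic-data factory

The generator emulates two study designs on samples of 2000 cases with nine
five-category items (or their numeric twins):

* **Scenario 1** (`make_scenario1()`): four exclusive subgroups of 500
  defined over three relevant covariates — `num1 < 100 & cat1 in {1,5}`,
  `num1 < 100 & cat1 in {2,3,4}`, `num1 >= 100 & cat2 <= 2`,
  `num1 >= 100 & cat2 >= 3` — plus five noise covariates (two numeric,
  three ordinal). Each subgroup's responses come from its own random
  parameter draw, so the model is true within subgroups and DIF is present
  overall. The structure is representable by a single depth-2 tree. `cat1`
  is declared unordered categorical: its planted rule is the non-contiguous
  subset `{1,5}`, which threshold splits on an ordered covariate cannot
  express, and exact four-leaf recovery is the designed outcome; `cat2`,
  whose rules are contiguous, stays ordinal.
* **Scenario 2** (`make_scenario2()`): two exclusive subgroups of 500 —
  `cat2 in {3,4} & num1 <= 50` and `dicho1 = 0 & cat1 in {1,4,5}` — and
  1000 cases of random responses (uniform categories 1..5, or Uniform(-3,3)
  numerically). The two rules involve disjoint covariate pairs, so no
  single binary tree isolates both while the forest can.

Parameter draws: thresholds iid N(0,1) sorted within item; latent variances
Uniform(0.5, 1.5); latent correlations Uniform(0.1, 0.5) projected to the
nearest positive-definite correlation matrix; intercepts N(0,1); residual
variances Uniform(0.5, 1.5). These ranges produce moderate, realistic
inter-item dependence and well-conditioned models; they are the generator's
fixed study conditions, recorded in every manifest. A drawn subgroup is
accepted only if its own-model fit (WLS for ordinal, ML for numeric) has
RMSEA at most 0.05, mirroring the design requirement that planted subgroups
fit their model well; the budget is 40 draws per subgroup and exhaustion is
an error, not a silent fallback. Covariates are drawn uniformly over each
subgroup's admissible region (rejection sampling keeps scenario-2 regions
exclusive), and rows are shuffled.

What the generator does *not* emulate: missing data, longitudinal dropout,
non-normal latent distributions, unequal subgroup sizes, and DIF that
shifts only a few items. Passing tests therefore show that the pipeline
recovers clean, well-separated parameter heterogeneity at survey-typical
sample sizes — not that it would detect subtle single-item DIF in messy
real data.

## Numerical choices and problem sizes

The test suite and the acceptance script re-measure the package's behavior
at desk scale, chosen to make the full run reproducible in minutes on one
core: 5–10 scenario-1 seeds per response scale for single-tree stability,
20 datasets of 10-tree forests per scale for recovery (the single-sample
forest application uses 50 trees, minimum node size 100, mtry 3, RMSEA
cutoff 0.05), 500 replicates for the family-wise null calibration, 100
random instances for the brute-force statistic oracles, and 2000 null
replicates for the LMuo quantile check. At these scales the binomial
standard error of a recovery fraction is about 0.1, which is the honest
resolution of the reported percentages.

Known limitations: full-information marginal ML estimation is out of scope
(the limited-information two-stage design exists precisely because the
full-information tree is computationally prohibitive); instability tests
for WLS-fitted models are unavailable, which is why leaves are evaluated
but not grown under WLS; categorical covariates are capped at 10 levels by
the exhaustive subset search; and the boundary-optimum handling described
above trades a sharply defined convergence criterion for robustness on
contaminated nodes.
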