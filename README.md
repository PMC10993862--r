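# mgrtree

Detecting differential item functioning (DIF) in multidimensional graded
response (MGR) and confirmatory factor analysis (CFA) measurement models by
model-based recursive partitioning — single decision trees and random-split
forest ensembles — with limited-information estimation.

## Who this is for

Survey methodologists and psychometricians working with multi-item ordinal
scales (Likert-type items) measuring one or several latent traits. If latent
scores are to be compared across groups, the item parameters must not depend
on respondent characteristics; when the relevant subgroups are unknown,
`mgrtree` searches for them over a set of covariates.

## The method

The probit cumulative model for ordered responses links item *i* and the
latent vector ξ through

    P(Y_i ≥ k | ξ) = Φ(β_i′ ξ − α_ik),

with thresholds α_ik increasing in *k*; the numeric counterpart is the CFA
model Y = π + β′ξ + ε. DIF means the item parameter vector depends on
covariates Z₁,…,Z_R.

A tree is grown in two stages:

1. **Growth (limited-information ML).** In each node the model is fitted by
   minimizing F_ML(θ) = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − m (ordinal
   responses are treated as numeric scores during growth — a deliberate
   compromise). Casewise scores ψ(y_j, θ̂) feed generalized M-fluctuation
   tests of parameter stability: **maxLM** for numeric covariates (supremum
   of ‖B(t)‖²/(t(1−t)) over cut points), **LMuo** for unordered categorical
   (χ² with k(C−1) df), **maxLMo** for ordered covariates. The covariate
   with the smallest Bonferroni-adjusted p-value below α splits the node;
   none significant ⇒ leaf.
2. **Evaluation (distribution-free WLS).** Each leaf of an ordinal tree is
   re-estimated from thresholds and polychoric correlations by minimizing
   F_WLS(θ) = [κ̂ − κ(θ)]′ Ŵ [κ̂ − κ(θ)] with Ŵ the inverse empirical
   asymptotic covariance of κ̂, yielding χ² = n·F_WLS, df, and
   RMSEA = √(max(χ²−df,0)/(df(n−1))) with a noncentral-χ² confidence
   interval.

The **forest** grows many trees on the full sample (no bagging; estimates
stay replicable), decorrelated by redrawing `mtry` candidate covariates at
every node. Leaves passing an RMSEA (or χ²-p) cutoff are pooled; subgroups
are identified by case sets, merged across trees with a frequency count and
subset-relation annotations.

A synthetic-data factory generates the two benchmark designs: scenario 1
(four covariate-defined DIF subgroups, recoverable by one tree) and
scenario 2 (two subgroups plus a random-response half, recoverable only by
an ensemble), in ordinal (probit multistate PIEG model) and numeric (CFA)
versions, with ground-truth manifests.

## Worked example

```r
library(mgrtree)

sc <- make_scenario1("ordinal", seed = 1)        # 2000 x 9 items + 8 covariates
tree <- mgr_tree(sc$data, sc$Z, sc$manifest$spec,
                 mgr_tree_control(seed = 1))
print(tree)
```

```
MGR model tree (score method): n = 2000, 4 terminal nodes
+ node 1: n = 2000, split on num1
  [num1 <= 99]
    + node 2: n = 1000, split on cat1
      [cat1 in {2,3,4}]
        * leaf 3: n = 500, WLS chi2 = 27.83 (df 21), RMSEA = 0.026
      [cat1 not in {2,3,4}]
        * leaf 4: n = 500, WLS chi2 = 26.47 (df 21), RMSEA = 0.023
  [num1 > 99]
    + node 5: n = 1000, split on cat2
      [cat2 <= 2]
        * leaf 6: n = 500, WLS chi2 = 23.74 (df 21), RMSEA = 0.016
      [cat2 > 2]
        * leaf 7: n = 500, WLS chi2 = 33.59 (df 21), RMSEA = 0.035
```

The tree recovers the four planted subgroups exactly: the root splits the
numeric covariate at its true boundary (99 ≡ num1 < 100), then the
categorical subset {1,5} and the ordinal threshold cat2 ≤ 2. Every leaf's
WLS refit fits well (RMSEA ≤ 0.05 with df = 21), as designed:

```r
classify_tree_stability(tree, sc$manifest)
#> [1] "stable"
```

For complex structure, grow an ensemble:

```r
sc2 <- make_scenario2("ordinal", seed = 3)
fo <- mgr_forest(sc2$data, sc2$Z, sc2$manifest$spec,
                 n_trees = 50, mtry = 3, cutoff_value = 0.05, seed = 3)
print(fo)   # fit-sorted subgroup report: rule, n, chi2, df, RMSEA, freq, subsets
```

The report lists recurring well-fitting subgroups sorted by fit. Both
planted subgroups are recovered with their exact case sets of n = 500
(rules equivalent to `cat2 in {3,4} & num1 <= 50` and
`dicho1 = 0 & cat1 in {1,4,5}`); the list also contains smaller
well-fitting leaves, most of them annotated as strict subsets of other
reports via the `subset_of` column — the signature that distinguishes a
planted subgroup from a random refinement.

A thin command-line front end over these functions ships in
`inst/scripts/mgrtree.R` (`simulate`, `tree`, `forest`, `recovery`
subcommands).

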