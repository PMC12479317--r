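---
title: "genetmle: models, estimators and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genetmle: models, estimators and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This note records the statistical model the package implements, the
defaults and conventions that matter in practice, the design choices made
where more than one reasonable option existed, and what the test suite
does and does not establish. It states no empirical result that the tests
or the acceptance script do not themselves compute.

## Model and estimands

The observed unit is `O = (W, A1, ..., Am, Y)`: confounders `W` (typically
genetic principal components), categorical treatments `A_i` (genotype
categories, discretized exposures), outcome `Y` continuous or binary
(0/1), plus outcome-only covariates `C` (age, sex) that enter the outcome
regression but not the propensity. No parametric restriction is placed on
the outcome law. The estimands are the covariate-adjusted counterfactual
mean at a joint level assignment, the ATE between two levels of one
treatment, and the k-point average interaction effect: the alternating sum
of counterfactual means over the 2^k corners ("vertices") of the
baseline-to-target hypercube, with sign `(-1)^(k - |s|)`. Vertices are
enumerated in lexicographic order of the binary index `s` for reproducible
reporting. A causal reading additionally needs positivity and no
unmeasured confounding; the package's own guarantees are about the
statistical functionals.

Treatment levels are opaque, explicitly ordered labels: allele strings
(`TT`, `TC`, `CC`) and integers (`0,1,2`) are both accepted, and nothing
constrains contrasts to adjacent levels — any declared pair is a valid
contrast. Individuals with missing values in any referenced column are
dropped listwise before estimation and the count is reported; no
imputation is attempted.

## Nuisance functions and learners

Two nuisances are fitted: the outcome regression `Qbar(A, W, C)` and the
propensity `g(a(s) | W)`. By default the joint propensity factorizes as a
product of per-treatment multinomial models — appropriate when interacting
variants are not in linkage disequilibrium, which is the regime the
simulation designs encode; a `joint_propensity` flag fits one model over
the joint categories instead for users who do not want the product
assumption.

Learners: `lrn_constant` (marginal mean; also the canonical deliberately
misspecified fit in double-robustness checks), `lrn_glm` (optionally with
all pairwise interaction columns, which saturates small discrete
problems), `lrn_glmnet` (ridge by default), `lrn_boost`, `lrn_stack` (a
super learner: out-of-fold predictions per base learner, then convex
simplex weights minimizing CV squared error / log-loss, fitted by
projected L-BFGS-B, or discrete winner-take-all selection), and
`lrn_hwe_glm`, a genotype-specific propensity model that fits the allele
count as `Binomial(2, expit(W b))` and converts to genotype probabilities
— the natural parametric model for a variant in Hardy-Weinberg
equilibrium given ancestry. A Highly Adaptive Lasso slot (`lrn_hal`)
exists but is intentionally unimplemented.

`lrn_boost` deserves a note: the environment this package targets has no R
gradient-boosted-tree library, so the boosted-tree slot is filled by a
small native implementation — gradient boosting of depth-1 regression
stumps with squared-error fits to pseudo-residuals and Newton leaf values
for binomial loss, deciles as candidate splits. It fills the same
methodological role (a flexible, overfit-prone learner whose overfitting
the cross-validated estimators must absorb); it is not a reimplementation
of any specific library.

Cross-fitting uses `k = 3` folds by default, stratified jointly on the
treatment categories and (for binary traits) the outcome, so every
training split sees all classes. For rare binary outcomes the helper
`adaptive_k_folds` implements `k = min(20, max(3, floor(rare/10)))` —
more folds when cases are scarce. Every stochastic step (fold shuffles)
takes an explicit seed.

## Targeting and the CV dialect

The fluctuation is an intercept-free one-parameter regression of `Y` on
the clever covariate with the initial `Qbar` as offset: identity link for
continuous outcomes (solved in closed form, so one step is exact and
`B_n` is zero to machine precision), logit link for binary outcomes
(IRLS, iterated to `|B_n| <= tol` with `tol = 1e-8 * sd(Y)` continuous /
`1e-8` binary, `max_iter = 10`; non-convergence sets a warning flag on
the record rather than failing). Canonical mode uses the
inverse-propensity clever covariate with unit weights; weighted mode
moves `1/g` into the regression weights and uses the signed indicator
covariate, which is the variant that behaves better near positivity
violations (rare genotypes). Binary-outcome predictions are clipped to
`[1e-6, 1 - 1e-6]` before the logit offset; propensities are clipped to
`[1e-5, 1 - 1e-5]` (`g_floor`). The clipping floor is a guard for the
division, not the positivity control: the primary control is contrast
pruning by marginal vertex frequency.

For the `cv_*` estimators the exact cross-validated construction admits
several published dialects and the one implemented here is the pooled
one: nuisances are cross-fit so each individual is scored by models that
never saw their fold, and then a *single* fluctuation (or a single pooled
bias correction for `cv_ose`) is applied over all held-out predictions,
with the variance computed from the pooled held-out EIF. This is one of
the standard choices; per-fold fluctuations averaged across folds are the
main alternative and are not provided.

Multi-contrast estimands (e.g. the joint `0->1`, `1->2` pair of one
variant) share one initial `Qbar` and propensity fit; each component gets
its own fluctuation, and the component EIFs are stored side by side for
the joint covariance. A single multidimensional fluctuation would also
solve the joint score but is not the default here.

Degenerate inputs: if no individual sits on any vertex after pruning the
estimand is skipped with a distinct `empty-support` condition class;
`sigma2 = 0` yields a flagged degenerate interval at the point estimate; a
singular joint EIF covariance falls back to a pseudo-inverse with reduced
rank and a warning.

## Inference defaults

Wald intervals and two-sided p-values throughout (`alpha = 0.05`).
The Hotelling statistic is referred to its exact
`p(n-1)/(n-p) F_{p,n-p}` distribution, not the chi-square limit.
Positivity pruning computes *unconditional* vertex frequencies (the
joint frequency of the level assignment across the k treatments) on the
analysis sample after listwise deletion, with threshold 0.01 by default;
only the failing contrasts are dropped, never whole estimands. Because it
is ambiguous whether per-vertex joint or per-treatment marginal
frequencies are the better operationalization for `k >= 2`, both are
exposed (`per_treatment` flag); the joint-vertex rule is the default and
is the more conservative of the two. Benjamini-Hochberg adjustment is
applied across the whole batch by default, with per-outcome scoping
configurable.

## Sieve-plateau variance

The GRM is the sample correlation of centred, scaled dosages over R
unlinked variants (with `1/(R-1)` normalization); monomorphic variants are
excluded with a warning, and an optional Hardy-Weinberg chi-square
pre-filter is provided but not enforced — variant selection is the
caller's responsibility. Dissimilarity is `d = 1 - G`. Conventions chosen
here and flagged in output metadata because sample GRMs are not ideal
correlation matrices: `d(i, i) := 0` (so the `tau = 0` estimator is
exactly the iid one, regardless of `G_ii != 1`), and off-diagonal `d < 0`
(possible for small R) is clamped to 0. The default grid is 100 equally
spaced thresholds in `[0, 1]`: at `tau` large enough to include all pairs
the double sum collapses to `(sum D)^2 / n`, which is ~0 for any
score-solving estimator, so the grid deliberately stops before that
degenerate region. The selected value is the grid argmax (first maximum
on ties), i.e. the most conservative estimate; because the grid contains
0, SVP-corrected p-values are never smaller than iid ones. Pair products
are accumulated in row chunks, so the n x n dissimilarity matrix is never
held whole. In batch runs the correction is applied only to rows whose
iid p-value falls below a trigger (default 0.07), since the correction
can only de-significate.

## What the synthetic generators do and do not emulate

The null design draws genotypes `Binomial(2, MAF)`, a standard-normal (or
Bernoulli) trait, and inert covariates, all mutually independent — the
sharp null where every genetic estimand is exactly 0. The confounded
design generates by ancestral sampling `PCs, C -> A -> Y`: allele
probability logistic in the PCs, genotype binomial given the allele
probability, outcome mean linear in PCs/age/sex with per-variant additive
dosage terms, optional dominance terms (non-linear allelic effects) and
dosage-product interaction terms, plus gaussian or Bernoulli noise. Where
the benchmark conditions state values they are used (6 PCs; MAF 0.3 and
n = 5000 with 300 replicates for the coverage target; `k = 3` folds);
remaining coefficients were chosen once at plausible genetic-epidemiology
scales (allelic effects 0.1-0.3 SD, confounder loadings 0.3-0.4) and are
not tuned.

The original benchmark for this methodology resamples a real biobank and
fits neural conditional-density estimators to it; this package replaces
that with the explicit parametric generators above, keeping the same
dependence graph. That is an emulation, not a replication: the generators
have exact Monte-Carlo ground truth but lack the empirical marginals,
linkage disequilibrium, cryptic relatedness and learned non-linearities
of real cohort data. A green coverage or double-robustness test therefore
establishes calibration under the stated parametric world — correct
dependence structure, known truth — and not performance on any real
biobank. Coverage is aggregated with normal-approximation binomial error
bars; 300 replicates (rather than 500) and n in the thousands (rather
than 5 x 10^5) keep the harness at desk scale.

## Known limitations

Continuous or time-varying treatments, mediation parameters, collaborative
or adaptive TMLE variants, permutation or Bayesian inference, and the HAL
learner are out of scope. The bounded (logistic) fluctuation for
continuous outcomes is not implemented — continuous outcomes always use
the linear fluctuation, so outcome scaling is never applied. The GRM is
held dense (fine up to tens of thousands of individuals; the sieve curve
itself is chunked). The multinomial GLM propensity is one-vs-rest
renormalized rather than a true multinomial likelihood; `lrn_glmnet` and
`lrn_hwe_glm` provide exact alternatives where that matters.
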