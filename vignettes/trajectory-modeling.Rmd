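---
title: "Latent trajectory modeling of 2-year clinical outcomes with trajmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent trajectory modeling of 2-year clinical outcomes with trajmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The problem

Cohorts followed through early intervention for a first episode of
psychosis are strikingly heterogeneous: positive symptoms, negative
symptoms and social/occupational functioning evolve along very different
paths in different people. trajmix models this heterogeneity with finite
mixtures of latent growth curves: each latent class `k` has a polynomial
mean trajectory, and a subject in class `k` contributes a multivariate
normal likelihood over their *observed* visits,

$$y_i \mid c_i = k \;\sim\; \mathcal N\!\big(X_i\beta_k,\;
  Z_i \Psi_k Z_i' + \Theta_k\big),$$

where `X_i` is the polynomial design at subject `i`'s observed visit
times (months), `Z_i` the random-effect design (intercept and/or linear
slope), `Psi_k` the growth-factor covariance and `Theta_k` a diagonal
residual matrix. The marginal likelihood is
$\sum_k \pi_k \,\phi_k(y_i^{obs})$, i.e. full-information maximum
likelihood (FIML): subjects contribute whatever visits they have, which
is valid when assessments are missing at random.

Constraining pieces of this model yields the familiar family ladder:

* **GCM** — one class, random effects: the sample mean trajectory.
* **GBTM** — classes, no random effects, one residual variance.
* **LCGA** — GBTM with residual variances relaxed over time and/or classes.
* **GMM** — classes plus random effects, with the growth-factor
  covariance shared (`class-invariant`) or free per class
  (`class-variant`).

Because the model is linear-Gaussian, random effects integrate out in
closed form; no numerical integration is used anywhere. Internally the
marginal density is evaluated through the Woodbury identity on the
(at most 2-dimensional) random-effect block, vectorized over subjects,
so missingness patterns cost nothing extra.

## Estimation

`fit_lgm()` maximizes the mixture likelihood by ECM: the E step computes
posterior class probabilities and the conditional moments of the random
effects; the CM steps update growth coefficients by weighted generalized
least squares, `Psi` and `Theta` in closed form, and `pi` from mean
posteriors. Every CM cycle is monotone in the observed-data likelihood.
Diagonal-covariance families (GBTM/LCGA) run in a compiled kernel
because the bootstrap test below refits thousands of them.

Mixture likelihoods are multimodal, so starts matter. The protocol
mirrors common mixture practice: initial responsibilities come from a
k-means partition of subject-level OLS growth coefficients, randomly
perturbed per start; all starts run a short exploratory EM, the best
quarter run to convergence, and the winner can be polished by BFGS on
the full likelihood. `start_protocol()` defaults to the reference
protocol of 500 starts with 125 finalists; the internal desk-scale
default uses 8 starts, which is ample at the class separations used
here. `fit_lgm_replicated()` implements the replication rule: two
independent runs must agree in best log likelihood within `1e-4`,
otherwise the number of starts is doubled (up to 3 doublings).

Numerical choices, all chosen for desk-scale determinism and declared
rather than inherited from any reference software: relative
log-likelihood tolerance `1e-8` (full protocol; `1e-7` in the compact
one) with a 2000-iteration cap; residual variances floored at
`1e-6 * var(y)` and the random-effect covariance kept positive definite
by an eigenvalue floor, both flagged in the convergence report when
active; time is rescaled internally (months/12) so cubic designs stay
well-conditioned, with all reported coefficients back-transformed to
month units; `Psi` is parameterized by its Cholesky factor during
quasi-Newton steps so positive-definiteness cannot be lost. Modal
assignments break posterior ties toward the lower class index.

## The four-stage selection strategy

`select_trajectory_model()` implements a systematic
least-constrained-last ladder:

1. a single-class growth curve baseline;
2. class enumeration with GBTMs (`K = 1..6` by default), the class
   structure chosen by BIC subject to admissibility — smallest modal
   class at least 5% of the sample, and a parametric bootstrap
   likelihood ratio test of `K` vs `K-1` at `alpha = 0.05`;
3. residual-variance relaxation (over time, classes, or both), BIC-best
   admissible kept;
4. stepwise random effects (class-invariant then class-variant,
   intercept then intercept+slope), BIC-best admissible kept;

followed by Wald-based pruning of the highest non-significant polynomial
term per class (refitting after every drop) and Mardia's multivariate
skewness/kurtosis test within modal classes of the final model
(complete cases only; small classes are reported "not assessable").

Scaled entropy and per-class APPA are always reported against the
conventional floors (0.5 and 0.7). They are advisory by default —
`floors_hard = TRUE` turns them into rejection rules — because in
practice accepted trajectory solutions routinely sit near or below the
entropy floor. Ties within 2 BIC points go to the fewer-parameter model,
honouring the "most parsimonious" goal.

The test of `K` vs `K-1` classes is a parametric bootstrap LRT: data
are simulated from the fitted `K-1` model (preserving each subject's
observed-visit pattern), both models are refit per replicate, and
`p = (1 + \#\{stat_b \ge stat_{obs}\})/(R+1)`. Attainable p values are
`1/(R+1), ..., 1`, so significance uses `p <= alpha`. Replicate refits
are warm-started at the generating and observed solutions with one
additional random start — the standard cost-saving device — and the
naive `-2ΔLL` is reported alongside.

## Manual 3-step covariate and distal-outcome analysis

Re-estimating the mixture with covariates included would let covariates
reshape the classes. The manual 3-step avoids that: step 1 fits the
unconditional model; step 2 summarizes the classification error of the
modal assignment as a column-stochastic matrix
`P(modal s | true k)` (average posterior mass construction) and its
logits; step 3 treats the modal class as an error-prone indicator with
that measurement matrix *fixed*, and estimates only the structural part
— a multinomial logistic regression of class on one covariate at a time
(`predict_membership()`), or class-specific means/thresholds of a distal
outcome with pairwise Wald chi-square equality tests
(`distal_outcome_test()`).

Because both the measurement matrix and the step-1 class proportions are
held fixed, adding a covariate cannot move the class distribution: the
reported proportions are invariant by construction, which is the
contract the 3-step is meant to provide. Standardized mean differences
divide the difference in estimated class means by the sample standard
deviation of the outcome. Boundary estimates (a class probability of 0
or 1) are reported as unbounded odds ratios with a flag rather than a
spurious finite number. `cross_trajectory_rr()` cross-tabulates two
modal classifications over shared subjects and reports Katz-CI risk
ratios; `bonferroni_adjust()` applies family-size corrections with the
family declared by the user.

## Clinical endpoints

`derive_endpoints()` operationalizes the 2-year endpoint battery: early
response (score at month 3 at most half of baseline; a zero baseline is
degenerate and satisfied only by a zero month-3 score), sustained
symptom remission (all global items at or below 2 — attention excluded
for the negative-symptom scale — at both months 18 and 24), functional
remission (functioning strictly above 60 at both months 12 and 24),
clinical remission (both symptom remissions) and recovery (clinical AND
functional remission). Windows are verified only at the scheduled visits
bounding them — no interpolation — matching how such criteria can
actually be checked on this schedule. Any endpoint with a required visit
missing is "not evaluable" (NA), never false; conjunctions use
three-valued logic so a definite FALSE dominates an NA. The "total
symptoms" early response uses the summed positive+negative series at
visits where both are observed; requiring both components separately is
available as an alternative reading by composing the per-scale flags.
`attrition_filter()` implements the sensitivity exclusion of subjects
missing more than 30% of scheduled visits.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws linked cohorts with the structure the analysis
assumes: 689 subjects; positive and negative symptom sums over 9 visits
(0,1,2,3,6,9,12,18,24 months) and functioning over 3 visits (0,12,24);
2/3/2 latent classes with mean curves interpolating the published
trajectory anchors (positive symptoms 9.8→4.2 and 3.0→1.1; negative
symptoms starting 9.2–9.8 and ending 4.8/5.7/6.8 with one linear class;
functioning 35.9→50 and 44.2→76.4); cross-outcome dependence through a
single shared standard-normal propensity with ordinal probit splits,
loadings calibrated by bisection so the symptom-functioning risk ratios
hit the published magnitudes (2.23 and 1.53); a binary employment
covariate with odds ratio 4.5 for the better functioning class and
continuous covariates (verbal memory, log-normal DUP) with
class-conditional shifts; distal outcomes drawn class-conditionally;
and missing-at-random visit masks whose hazard increases with time and
depends on the observed employment covariate, with intercepts solved to
hit 30% (symptoms) / 34% (functioning) overall missingness. Symptom
scores are truncated at the valid range after noise addition and the
truncation rate is reported. Global-item vectors at months 18/24 are
integer splits of the rounded sums capped at 5 per item, so remission
criteria are derivable. Everything is a deterministic function of one
seed.

Two deliberate departures from realism deserve emphasis. First,
within-class variances are nowhere published, so they are free
parameters of the generator. They are calibrated mildly: small
random-effect variances and near-homogeneous residuals for the
positive-symptom outcome. The reason is structural, not cosmetic —
class-*number* recovery by single-variance GBTM enumeration is only
well-posed when within-class heterogeneity departs modestly from the
enumeration model. With strong random effects or strongly
class-dependent residual variances, BIC provably prefers extra classes
that absorb the covariance structure (a well-documented behaviour of
group-based enumeration), and no selection pipeline that fixes `K` at
the GBTM stage can then recover the generating count. Real cohorts
almost certainly carry more within-class structure than this generator;
passing the round-trip suite therefore demonstrates correctness of the
machinery under the stated conditions, not that class enumeration on
real data is this well-behaved. Second, classification entropy of the
fitted positive-symptom solution runs higher (~0.9) than the published
0.81, a side effect of the mild-heterogeneity calibration; the
negative-symptom (~0.6 vs 0.43) and functioning (~0.55 vs 0.51)
solutions sit close to the published certainty. The generator does not
emulate item-level response processes, integer scoring of the sums,
informative dropout, or rater effects.

The published SAPS/SANS global-score ranges are not fully pinned down
(the sums may cover 4 or 5 global items); the generator uses 4 global
items for the positive scale and 5 (attention included, sum range 0–25)
for the negative scale, and `lgm_data()` takes the valid range as an
argument rather than fixing it.

## Problem sizes used by the test suite

The validation suite exercises the full pipeline at the study's scale
but with compact stochastic budgets, stated here as the package's own
choices: parameter recovery uses 20 cohorts of N = 600; structure
recovery 20 cohorts of N = 689 with 49 bootstrap replicates per LRT;
type-I-error calibration 200 repeats of a 99-replicate LRT at N = 100
on a 3-visit schedule; and candidate fits use the compact 6–8-start
protocol. The replication rule and the 500-start reference protocol
remain available for final confirmatory fits.

## Known limitations

* Outcomes are modeled as conditionally Gaussian; bounded, skewed or
  integer-valued scores are handled only through the normality check
  flagging affected classes, not through skew-t or censored families.
* Residual covariance over time is diagonal within class; autoregressive
  structures are out of scope.
* Covariates enter one at a time (the 3-step as published); joint
  covariate models and BCH weighting are not implemented.
* The bootstrap LRT is the operative enumeration test; the analytic
  Lo–Mendell–Rubin adjustment is not reproduced.
* Standard errors come from the observed information of the polished
  optimum; no sandwich correction is applied.
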