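# trajmix

Latent trajectory analysis of longitudinal clinical outcomes by growth
mixture modeling, built for 2-year first-episode-psychosis follow-up
designs but applicable to any cohort measured repeatedly on a fixed
visit schedule.

Outcomes after a first episode of psychosis are heterogeneous: symptom
and functioning curves differ qualitatively between patients, and a
single mean trajectory misleads. `trajmix` models a long-format outcome
table as a finite mixture of latent growth curves. Class *k* has
polynomial mean curve `X β_k`; a subject in class *k*, observed at
visits `t_ij`, contributes

    y_i | c_i = k  ~  N( X_i β_k ,  Z_i Ψ_k Z_i' + Θ_k )

restricted to observed visits (full-information maximum likelihood,
valid under missing-at-random assessments), and the marginal likelihood
is `Σ_k π_k φ_k(y_i)`. Constraining Ψ and Θ gives the standard families:
growth curve model (GCM, one class), group-based trajectory model
(GBTM), latent class growth analysis (LCGA), and growth mixture models
with class-invariant or class-variant random effects (GMM).

On top of estimation, the package implements the surrounding analysis
workflow:

* **Four-stage model selection** — GCM baseline; GBTM class enumeration
  under BIC, a parametric bootstrap likelihood ratio test, the <5%
  smallest-class rule and entropy/APPA reporting; residual-variance
  relaxation; stepwise random-effect addition; Wald-based pruning of
  polynomial orders; within-class Mardia normality checks. Every fitted
  candidate lands in an audit table.
* **Manual 3-step association analysis** — misclassification logits
  extracted from the fitted model; covariate effects (odds ratios) and
  distal-outcome contrasts (Wald chi-square, standardized mean
  differences) estimated with the class structure held fixed, so the
  class distribution cannot shift; cross-trajectory risk ratios with
  Katz confidence intervals; Bonferroni family corrections.
* **Clinical endpoints** — early response (50% symptom reduction by
  month 3), sustained symptom remission (global items ≤ 2 at months 18
  and 24, attention excluded for negative symptoms), functional
  remission (score > 60 at months 12 and 24), clinical remission and
  recovery, all with explicit "not evaluable" handling; a >30%-missing
  attrition filter for sensitivity analyses.
* **A synthetic cohort generator** — linked positive-symptom,
  negative-symptom and functioning trajectories with 2/3/2 latent
  classes anchored to published trajectory values, cross-outcome
  dependence calibrated to published risk-ratio magnitudes,
  class-conditional covariates and distal outcomes, and
  missing-at-random visit masks, all deterministic given one seed.

Everything is tidyverse-native: functions take data frames, return
tibbles, and fitted objects have `tidy()`, `glance()`, `augment()` and
`autoplot()` methods.

## A worked example

Generate a study-scale synthetic cohort and run the full selection
ladder on the functioning outcome:

```r
library(trajmix)

cohort <- generate_cohort(cohort_config(n_subjects = 689, seed = 1))
cohort
#> <synthetic_cohort> 689 subjects, seed 1
#>   SAPS   K = 2 (462/227), observed 4340/6201 visits (30% missing)
#>   SANS   K = 3 (313/100/276), observed 4366/6201 visits (30% missing)
#>   SOFAS  K = 2 (387/302), observed 1384/2067 visits (33% missing)

sel <- select_trajectory_model(
  cohort$outcomes$sofas$data, preset_poly_order = 2,
  config = selection_config(lrt_replicates = 49), seed = 1)
sel
#> <lgm_selection>
#>   selected: GBTM, K = 2, orders 2/2, residuals FIXED
#>   loglik -5357.58, BIC 10767.4, entropy 0.654
#>   audit: 16 candidates/decisions recorded

tidy(sel$fit)
#> # A tibble: 6 × 4
#>   class proportion term  estimate
#>   <int>      <dbl> <chr>    <dbl>
#> 1     1      0.413 t^0    43.8
#> 2     1      0.413 t^1     3.13
#> 3     1      0.413 t^2    -0.0740
#> 4     2      0.587 t^0    35.8
#> 5     2      0.587 t^1     1.50
#> 6     2      0.587 t^2    -0.0369
```

The selected model is the generating one: a 2-class quadratic GBTM with
a single residual variance. Class 1 (41%) rises from ~44 toward good
functioning; class 2 (59%) stays at moderate impairment — the fitted
curves recover the generating anchors (44.2→76.4 and 35.9→50). The
audit table (`sel$audit`) records every candidate with its BIC, entropy,
APPA, smallest-class share, LRT p value and the decision taken.

Associate baseline employment with trajectory membership while keeping
the class structure fixed (manual 3-step):

```r
eff <- predict_membership(sel$fit, cohort$covariates, "non_neet",
                          reference_class = 2)
dplyr::select(eff, covariate, class, estimate, conf_low, conf_high, p_value)
#> # A tibble: 1 × 6
#>   covariate class estimate conf_low conf_high  p_value
#>   <chr>     <int>    <dbl>    <dbl>     <dbl>    <dbl>
#> 1 non_neet      1     4.50     2.88      7.02 3.34e-11
```

Being employed/in education at baseline multiplies the odds of the
improving trajectory by 4.5 (the generator's built-in effect), with the
class distribution identical to the unconditional model by construction.

`run_pipeline(run_config(...))` chains the whole analysis — selection
per outcome, endpoints, 3-step covariates and distal outcomes,
cross-trajectory risk ratios, optional attrition-filter sensitivity
rerun — and writes CSV tables plus a JSON manifest that makes the run
bit-for-bit reproducible.

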