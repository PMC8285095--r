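# pvlbayes

Decision making on the Iowa Gambling Task (IGT), decomposed. `pvlbayes`
is an R package for researchers who want to go beyond net scores: it
implements the Prospect Valence Learning (PVL) family of
reinforcement-learning models of IGT choice, hierarchical Bayesian
estimation of their four decision parameters, model selection by DIC,
and Bayesian regression of real-world outcomes (for example
substance-related health-risk indices) on those parameters with the full
posterior uncertainty propagated through — plus a seeded synthetic
cohort generator so every stage can be validated against known ground
truth.

## The model in brief

On each trial a net outcome `x` (gains − losses, in hundreds of points)
is valued by a prospect-theory utility

    u(x) = x^alpha            if x >= 0
    u(x) = -lambda * |x|^alpha  if x < 0

with `alpha` in [0, 1] (**attention to magnitude**) and `lambda` in
[0, 5] (**attention to losses**; 1 = symmetric, 0 = losses ignored).
Deck expectancies `E_j` update by a **delta** rule
(`E ← E + A (u − E)` for the chosen deck) or a **decay** rule
(`E ← (1 − A) E` for all decks, `u` added to the chosen one), with
**retention** `A` in [0, 1] (larger = faster updating). Choice is a
softmax over `theta * E_j`, with sensitivity `theta(t) = (t/10)^c`
(trial-dependent, **consistency** `c` in [−5, 5]) or `theta = 3^c − 1`
(trial-independent, `c` in [0, 5]). The four rule combinations are
PVL-Delta-TD, PVL-Delta-TI, PVL-Decay-TD and PVL-Decay-TI.

Subject parameters get truncated-normal group distributions (uniform
priors on group means over the parameter ranges, Inverse-Gamma(5, 1) on
group variances) and are estimated by adaptive MCMC; outcome regressions
use improper uniform coefficient priors and an Inverse-Gamma(3, 3)
residual-variance prior, drawing one joint PVL posterior sample per
iteration so coefficient intervals reflect parameter uncertainty.

## Worked example

Generate a synthetic cohort with known ground truth, fit the best-known
variant, compare against tradition, and regress an outcome on the
decision parameters:

```r
library(pvlbayes)

cohort <- generate_cohort(
  cohort_config_calibration(n_subjects = 20, n_trials = 100), seed = 42)

igt_scores(cohort$trials)
#> # A tibble: 20 × 10
#>   subject_id n_trials prop_advantageous prop_advantageous_last60 ...
#> 1 s001            100              0.25                    0.15
#> 2 s002            100              0.59                    0.617
#> 3 s003            100              0.55                    0.65

fit <- fit_pvl_hba(cohort$trials, pvl_model("delta", "td"),
                   chains = 4, iterations = 1000, burn_in = 500, seed = 7)
tidy(fit)
#> # A tibble: 8 × 6
#>   term                  estimate std.error conf.low conf.high  rhat
#> 1 mu_retention            0.0659    0.0576 0.000886     0.210 1.02
#> 2 mu_consistency          0.380     0.126  0.126        0.622 1.00
#> 3 mu_attn_losses          0.639     0.242  0.111        1.03  1.02
#> 4 mu_attn_magnitude       0.361     0.234  0.0194       0.870 1.01
#> # ... sigma2_* rows elided
```

`tidy()` rows are the group-level posterior: the cohort's mean attention
to losses is estimated at 0.64 with 95% credible interval [0.11, 1.03]
(this generator preset draws it around 0.89), and every R-hat sits at or
very close to 1.00, the usual convergence yardstick. `pvl_dic(fit,
cohort$trials)` reports mean deviance 4847, effective parameters 39 and
DIC 4886 for this fit; refitting the other three variants and calling
`compare_models()` ranks them by DIC (smaller is better on the same
data).

```r
reg <- propagate_regression(fit, cohort$subjects,
                            chains = 4, iterations = 1000, burn_in = 300,
                            seed = 9)
tidy(reg)
#> # A tibble: 5 × 6
#>   term           estimate std.error conf.low conf.high  rhat
#> 1 (Intercept)      -0.830     0.754   -2.34      0.665 1.000
#> 2 retention         0.763     1.75    -2.77      4.23  1.00
#> 3 consistency       0.679     0.557   -0.422     1.85  1.000
#> 4 attn_losses       0.163     0.641   -1.13      1.44  1.00
#> 5 attn_magnitude    0.171     1.10    -2.02      2.29  1.00
```

This cohort was generated with no decision-parameter effects on the
outcome, and correctly every 95% credible interval overlaps zero — the
intervals are wide precisely because each subject's parameters are
uncertain and that uncertainty is propagated rather than plugged in.

Health-risk outcome construction works from long-format use and
behavior tables:

```r
tabs <- generate_substance_tables(cohort$subjects$subject_id, seed = 3)
health_risk_outcomes(tabs$use, tabs$behaviors)
# per subject: harm_composite, map_index (0-4), health_risk_index
# (an exact cohort z-score), and per-substance tertile codes 0-3
```

Plots: `plot_block_curves(igt_block_curve(cohort$trials))` for learning
curves, `autoplot(fit)` for group posteriors, `autoplot(reg)` for
coefficient intervals.

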