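---
title: "Decomposing Iowa Gambling Task decision making: models, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing Iowa Gambling Task decision making: models, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvlbayes)
```

## The scientific problem

The Iowa Gambling Task (IGT) asks a participant to draw 100 cards from
four decks. Decks A and B pay a constant 100 points per card but lose
1250 points over every 10-card cycle (net −250); decks C and D pay 50
points per card and lose only 250 per cycle (net +250). Learning to
prefer C and D is the operational definition of advantageous decision
making. Traditional summaries — the net score, per-deck selection
proportions, and learning curves over five blocks of 20 trials — describe
*how well* someone performs but not *why*. The Prospect Valence Learning
(PVL) model family decomposes performance into four interpretable
component processes, and this package implements the full analysis
pipeline around that decomposition: task scoring, the four PVL variants,
hierarchical Bayesian estimation, model comparison by DIC, regression of
real-world outcomes on the decision parameters with full posterior
uncertainty carried through, the construction of substance-related
health-risk outcome variables, and a synthetic cohort generator that
makes every stage testable against known ground truth.

## The PVL model family

On trial $t$ a net outcome $x(t)$ (gains minus losses, in hundreds of
points) is evaluated by a prospect-theory utility

$$u(t) = \begin{cases} x(t)^{\alpha} & x(t) \ge 0 \\
 -\lambda\, |x(t)|^{\alpha} & x(t) < 0 \end{cases}$$

where $\alpha \in [0,1]$ (*attention to magnitude*) bends utility toward
or away from outcome size and $\lambda \in [0,5]$ (*attention to
losses*) weights losses relative to gains ($\lambda = 1$ is symmetric;
$\lambda = 0$ ignores losses entirely). Deck expectancies $E_j$ start at
zero and are updated by one of two rules governed by the *retention*
parameter $A \in [0,1]$:

* **delta**: $E_{chosen} \leftarrow E_{chosen} + A\,(u - E_{chosen})$,
  unchosen decks unchanged;
* **decay**: $E_j \leftarrow (1-A)\,E_j$ for all decks, then
  $E_{chosen} \leftarrow E_{chosen} + u$.

In both rules larger $A$ means faster updating — shorter retention of
past outcomes — so the parameter reads identically across rules. Choice
follows a softmax over $\theta E_j$ with sensitivity $\theta$ set by the
*consistency* parameter $c$ under one of two rules:
trial-dependent $\theta(t) = (t/10)^c$ with $c \in [-5,5]$ (positive
$c$: choices track expectancies ever more tightly as the task
progresses), or trial-independent $\theta = 3^c - 1$ with $c \in [0,5]$.
Crossing the two learning rules with the two choice rules gives the four
variants PVL-Delta-TD, PVL-Delta-TI, PVL-Decay-TD and PVL-Decay-TI.

Outcomes are divided by 100 before entering the utility function. This
is a pure numerical convenience — $x^\alpha$ on raw point values spans
many orders of magnitude across $\alpha$ — and the constant is an
explicit argument (`outcome_scale`) recorded with every likelihood
evaluation.

## Hierarchical estimation

Subject-level parameters are modelled as independent normals truncated
to the ranges above; group-level means carry uniform priors over exactly
those ranges and group-level variances carry Inverse-Gamma(5, 1) priors
(mean 0.25), which keeps prior mass on realistic between-subject spreads
rather than the heavy tails a half-Cauchy would allow. The sampler
behind `fit_pvl_hba()` is an adaptive Metropolis-within-Gibbs: subjects
are updated one parameter column at a time against the compiled
likelihood (subjects are conditionally independent, so acceptance is per
subject), group means and variances get scalar random-walk updates (the
variance on the log scale with the Jacobian included), and proposal
scales adapt in batches of 50 during burn-in only, so the kept draws
come from a fixed transition kernel. Chains initialise at jittered range
midpoints with variances at the prior mean, and re-draw the jitter up to
a retry cap if the starting log-posterior is not finite. Everything is
reproducible from one master seed, from which each chain derives its own
stream.

Desk-scale defaults are 4 chains of 2,000 kept draws after 1,000
burn-in; study-scale settings — 4 chains of 75,000 kept after 25,000
burn-in, 300,000 combined draws — are plain argument changes
(`mcmc_plan(4, 75000, 25000)` does the bookkeeping). Convergence is
monitored by `gelman_rubin()` ($\hat R = \sqrt{\hat V / W}$, flagged
undefined for degenerate chains rather than silently 1) and `geweke()`
(early-versus-late window z-score with AR-fit spectral variance
estimates); `check_convergence()` warns above 1.02 and fails above 1.1.

Model variants are compared with the deviance information criterion,
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, where
$\bar D$ averages the deviance over all kept subject-parameter draws and
$D(\bar\theta)$ evaluates it at per-subject posterior means. The point
estimator for $D(\bar\theta)$ is a genuine choice — posterior means of
the constrained parameters — and is recorded in the result; draws with
non-finite deviance are excluded and counted, with more than 1%
exclusions treated as an error.

## Propagating posterior uncertainty into regression

Regressing an outcome on point estimates of the decision parameters
would ignore how uncertain those estimates are. `propagate_regression()`
instead runs a two-stage Gibbs scheme: each MCMC iteration takes one
stored joint draw of all subjects' PVL parameters (preserving
cross-subject posterior correlation), rebuilds the design matrix, and
draws the regression parameters conditional on it. Coefficients carry
improper uniform priors; the residual variance carries an
Inverse-Gamma(3, 3) prior (mean 1.5, variance 2.25 — the expectation of
a reasonably well-fitting model on a standardized outcome). Under these
priors the conditional structure is known exactly — $\sigma^2$ marginal
to the coefficients is Inverse-Gamma$(3 + (n-k)/2,\; 3 + \mathrm{SSE}/2)$
and $\beta \mid \sigma^2$ is normal around the least-squares solution —
so the default backend draws them exactly; a random-walk
Metropolis-Hastings backend is retained and agrees on posterior means
within Monte-Carlo error. The stream of PVL draw indices is generated
per chain before any regression randomness, so different outcome
specifications run under the same seed reuse identical PVL parameter
draws. Summaries report posterior means, posterior SDs and central 95%
credible intervals computed by linear interpolation between order
statistics (R's type-7 quantile rule, fixed so intervals are
reproducible); predictors enter on their natural scales unless
`standardize = TRUE`.

One subtlety is worth stating because it shaped the validation suite.
"Propagation never shrinks uncertainty" is true in the law-of-total-
variance sense: the propagated posterior variance of a coefficient
dominates the *average* conditional variance across fixed designs drawn
from the PVL posterior. It is *not* guaranteed against a fixed design at
per-subject posterior means: hierarchical shrinkage compresses the
dispersion of posterior-mean predictors, which inflates that design's
standard errors beyond the propagated ones. The width test therefore
compares against fixed designs taken at individual posterior draws,
whose predictor dispersion matches what propagation averages over.

Supporting utilities mirror common practice around such regressions:
`covariate_screen()` flags demographics correlated with the outcome at
p < 0.10 (Pearson; point-biserial for binary indicators),
`exploratory_correlations()` applies a Bonferroni gate of 0.05/k, and
`em_impute_items()` fills sparse questionnaire-item missingness with
conditional expectations under a multivariate-normal working model.

## Health-risk outcome construction

`health_risk_outcomes()` reproduces a harm-weighted outcome battery:

* **monthly harm score** — published harm-to-self weights per substance
  (shipped in `inst/extdata/harm_indices.csv`; tobacco 37.3, alcohol
  56.1, crack cocaine 79.5, …) multiplied by days of use per 28-day
  month and summed over substances; months reported on another length
  are normalised to a 28-day rate first;
* **harm composite** — the mean over the months of data available;
* **MAP index** — four risk behaviors (needle-sharing, unprotected sex,
  pipe-sharing, injection drug use) dichotomised over the year and
  summed to 0–4, invariant to how often a behavior recurs;
* **Health-risk Index** — each component z-scored within the cohort,
  averaged, and the average re-standardised, so the output is an exact
  cohort z-score. The phrase "standardizing the mean of" the two
  components is ambiguous between this and z-scoring a raw average;
  the default guarantees the documented z-score property and the
  alternative is available behind `method = "average_then_z"`;
* **frequency codes** — non-users 0, users split into rank tertiles
  1/2/3. Tied frequencies share an average rank and therefore a code:
  tie integrity deliberately outranks exactly balanced group sizes.
  With fewer than three users the same average-rank rule applies and
  simply yields the degenerate tertiles.

Tobacco and prescribed methadone enter the composite like any other
substance, since both carry published harm weights; an exclusion list
argument is provided for sensitivity analyses.

## The synthetic cohort generator

`generate_cohort()` draws per-subject parameters from truncated normals
with configured group moments, simulates choice sequences from the
configured model variant on the canonical payoff schedule, and builds
outcomes from a linear model with configurable coefficients (zero by
default, emulating null effects) plus normal noise with SD 1, matching
the regression's working model. Two presets encode the qualitative
contrast the pipeline is designed to resolve: a *community-style*
cohort (attention to losses centred near 0.19 with little spread, flat
learning) and a *calibration-style* cohort (attention to losses near
0.9 with wide spread, rising learning curves); demographic distributions
follow the same presets (age 43 ± 9.5 vs 22 ± 6.5 years, 21% vs 70%
female). Group SDs are set to IQR/1.35 of the corresponding reported
interquartile ranges — the normal-theory conversion — and a generated
sensation-seeking score correlates with the outcome at a configurable
target (default 0.28, i.e. about 8% shared variance). All randomness
derives from the master seed through per-subject, per-domain
sub-streams, so regeneration is byte-identical and adding subjects never
perturbs existing ones. `generate_substance_tables()` emulates the
structure of real use data with zero-inflated binomial days out of 28
(a mean of 28 sits exactly at the ceiling) and behavior indicators drawn
at published prevalences.

What the generator does *not* emulate: attrition and visit scheduling,
within-subject autocorrelation of monthly use, reporting bias, and any
dependence of IGT behavior on the outcome process beyond the configured
linear effects. Passing tests therefore demonstrate that the pipeline
recovers what it is pointed at under its own working model, not that the
working model captures all features of real cohort data.

## Validation strategy and problem sizes

The suite validates each layer against an independent oracle: the
compiled likelihood against a naive per-trial loop on 200 random
parameter/sequence pairs (tolerance 1e−10); trend contrasts against
one-sample t-tests on contrast scores; the diagnostics against
independently coded textbook formulas and against `coda`; the
health-risk constructions against spreadsheet-style hand computations on
small fixtures; EM imputation against a closed-form conditional-normal
fixed point. End-to-end checks run at sizes chosen to keep the full
suite in the minutes range while leaving the estimator honest work:
parameter recovery on 50 subjects × 100 trials with 4 chains × 2,000
kept draws (rank correlation above 0.5 for retention and attention to
losses, group means covered for at least three of four parameters);
model recovery on ten 40-subject cohorts at 2 × 600 kept draws (DIC
selects the generating PVL-Delta-TD variant in the majority); null
calibration on sixty 300-subject cohorts (95% credible intervals cover
zero at approximately the nominal rate). Recovery simulations use the
calibration-style preset: rank-correlation recovery is only a meaningful
yardstick when subjects genuinely differ, and the community preset's
attention-to-losses spread (SD ≈ 0.08) is deliberately narrow.

## Numerical choices and limitations

Softmax probabilities and the log-likelihood are computed with
max-subtraction, so extreme $\theta E_j$ products saturate gracefully
instead of overflowing; a choice can only receive log-probability
−infinity through genuinely degenerate inputs, and such draws are
counted and bounded in the DIC. Blocks are 1-based with block $b$
covering trials $20(b-1)+1$ to $20b$; partial final blocks are dropped
with a message. Two late-window conventions coexist in practice
("last 60 trials" versus "trials 21–100"), so `igt_scores()` reports
both rather than choosing; windows extending beyond a short sequence are
returned as `NA`, never extrapolated. The random-walk sampler trades the
per-iteration efficiency of a gradient-based sampler for having no
dependencies beyond the compiled likelihood; at desk scale its effective
sample sizes are ample (group-level $\hat R$ at or very close to 1.00),
but study-scale runs take correspondingly longer. DIC is the only model
comparison offered, matching the analysis it mirrors; WAIC or LOO would
require per-observation likelihood storage the fit object does not keep.
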