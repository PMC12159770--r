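---
title: "Risk-adjusted benchmarking of inpatient antibiotic use: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adjusted benchmarking of inpatient antibiotic use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Stewardship programs benchmark hospitals on antibiotic consumption. The
basic metrics are days of therapy (DOT — one count per agent per calendar
day administered, so combination therapy counts each agent) and days of
antimicrobial spectrum coverage (DASC — agent-days weighted by a positive
spectrum score), both normalized per 1000 days present (DP). Crude rates
confound stewardship with case mix; a credible comparison must risk-adjust,
and the package implements three adjustment levels side by side so their
effect on hospital *rankings* can be quantified:

* **crude** facility rates per 1000 DP;
* **method 1**: negative binomial regression on unit × month totals with a
  `log(DP)` offset and facility/unit factors only (the modeling approach of
  the NHSN SAAR), scored as observed-to-expected (O:E) ratios;
* **method 2**: a patient-level zero-inflated negative binomial (ZINB)
  model with hospital random intercepts in both components, scored as
  predicted-to-expected (P:E) ratios.

Both model families are fitted on a *baseline* period, frozen, and applied
to an *evaluation* period, so that a hospital's own recent data cannot
move the yardstick it is judged against.

# Method 2 in detail

For stay $i$ in hospital $h$ with covariate vectors $x_z, x_c$ and exposure
$d_i$ (DP):

$$\Pr(Y_i = 0 \mid b) = \pi_i + (1-\pi_i)\left(\tfrac{\theta}{\theta+\mu_i}\right)^\theta,
\qquad \Pr(Y_i = y > 0 \mid b) = (1-\pi_i)\,\mathrm{NB2}(y;\mu_i,\theta),$$

with $\pi_i = \mathrm{logit}^{-1}(x_z'\beta_z + \gamma \log d_i + b_{z,h})$
and $\mu_i = \exp(x_c'\beta_c + \log d_i + b_{c,h})$. DP is an offset in the
count component but a *regular* covariate in the zero component: longer
stays mechanically accumulate more DOT given use (offset), while the
probability of any use is a free function of length of stay (regular term,
entered as $\log d$ for consistency with the offset scale).

The hospital intercepts $(b_{c,h}, b_{z,h})$ are modeled as independent
zero-mean normals with variances $\sigma_c^2, \sigma_z^2$. We deliberately
do **not** estimate a cross-component covariance: the correlation between
the two intercepts is a *finding* to be examined post hoc
(`intercept_correlation()`), not a modeling assumption; estimating it would
partially absorb the very structure being reported. The synthetic generator
nevertheless supports a true cross-component correlation `rho` so the post
hoc estimate can be validated against ground truth.

## Likelihood, Laplace approximation, and its validation

The marginal likelihood integrates each hospital's intercept pair over its
normal prior — a 2-D integral per hospital. `fit_zinb_mixed()` maximizes a
per-hospital Laplace approximation: an inner Newton ascent (analytic
gradient, finite-difference Hessian of that gradient) finds the joint
posterior mode of $(b_c, b_z)$, and the log-integral is approximated by the
mode value plus the Gaussian curvature correction. The outer problem —
$(\beta_c, \beta_z, \log\theta, \log\sigma_c^2, \log\sigma_z^2)$ — is
solved by L-BFGS-B with bounds on the log-scale parameters
($\log\sigma^2 \in [-10, 3]$, $\log\theta \in [-4, 8]$) so boundary fits
($\hat\sigma^2 \to 0$) terminate cleanly; such fits are flagged
(`$boundary`) but remain valid. Warm starts come from unmixed Poisson and
logistic component fits; inner modes are cached between outer iterations.

The approximation is validated two ways in the test suite: against dense
2-D grid integration (an independent pure-R implementation of the stay
likelihood, 181–201 nodes per dimension over ±7 prior SDs) to within 0.1%
relative error at the 6-hospitals × 30-stays scale, and against `glmmTMB`
(fixed effects, variance components, marginal log-likelihood and BLUPs) on
moderate cohorts. `glmmTMB` is never used as the implementation — it is the
cross-check.

## Scoring: BLUPs and the P:E ratio

Evaluation-period scoring freezes $\hat\beta, \hat\theta, \hat\sigma^2$ and
re-estimates only the hospital intercepts on evaluation stays
(`reestimate_blups()`, posterior modes — BLUPs). Each stay then gets two
estimates: *predicted* $(1-\pi_b)\mu_b$ with the hospital's BLUPs in both
linear predictors, and *expected* $(1-\pi_0)\mu_0$ with intercepts set to
zero (the "standardized hospital"). The facility P:E is the ratio of their
facility sums. We use the mixture mean rather than the count-component mean
so that predicted totals are commensurable with observed totals; the
alternative (count mean alone) would benchmark only intensity-given-use and
is available by composing `expected_outcome()` by hand.

Because BLUPs are posterior modes under the $N(0,\sigma^2)$ prior, a small
hospital's intercept shrinks toward zero and its P:E toward one; the test
suite verifies both the consistency (BLUP → truth as stays grow) and the
specificity consequence: in a null cohort, small hospitals fall outside
[0.8, 1.25] more often under O:E than under P:E.

## DASC as a count outcome

Spectrum weighting makes DASC non-integer in general. The models treat DASC
by rounding to the nearest integer before evaluating the NB2 likelihood —
the pragmatic choice that preserves the count machinery; at DASC's scale
(several times DOT) the rounding perturbation is far below sampling noise.
The synthetic generator emits integer DASC directly (see below), so in
tests the rounding is a no-op.

# Variable selection

Patient-level flags first pass a prescreen: prevalence ≥ 0.5% and a
significant univariate association with the outcome per 1000 DP. The
association test is a Spearman rank correlation at α = 0.05 (the
correlation statistic is not otherwise pinned down by convention; Spearman
is robust to the zero-heavy, skewed rate distribution), with a union rule
across DOT and DASC so both models draw from one candidate list.

Selection for the two ZINB components uses the LASSO. A jointly penalized
ZINB is not a standard estimator, so `lasso_select_zinb()` alternates
(count → zero, ≤ 5 cycles): a weighted penalized Poisson regression with
`log(DP)` offset for the count component, weighting each stay by the
current probability that its zero is *not* structural; a penalized logistic
fit to those working structural-zero probabilities (with `log(DP)`
unpenalized) for the zero component; and a moment re-estimate of θ linking
the two. The penalty is chosen by BIC along a 50-value path — deterministic
and fast; 10-fold cross-validation is available (`lambda_rule = "cv"`).

`consensus_select()` partitions stays into K = 10 random subsets,
*stratified by hospital* so each subset retains every hospital (keeping
random intercepts estimable per subset), runs the selection per subset, and
keeps the strict K-way intersection. An empty consensus is a legal outcome
(warning, not error). Facility- and unit-level factors are then offered to
`backward_aic()`: starting from the full model, the candidate whose removal
most lowers AIC is dropped until no removal lowers it; patient-level terms
are never dropped; categorical factors enter and leave whole. For method 2
a facility candidate enters both components jointly — the component
placement of facility terms is otherwise a free choice, and the joint
treatment matches how such factors are reported (one decision per factor).

# The synthetic cohort generator

`simulate_cohort()` is the package's data source. It emulates: a hospital →
unit → stay hierarchy (first unit is the ICU; stays' `icu_stay` /
`surgical_specialty` follow their unit), sparse Bernoulli comorbidity and
procedure flags, DP from a shifted negative binomial (median ≈ 5 days),
calendar months spanning a 24-month baseline and 12-month evaluation
period, and ZINB outcomes exactly as method 2 assumes, with per-hospital
intercept pairs drawn bivariate-normal (`rho`, default 0.5 in demo
scenarios, 0 in estimation tests).

Defaults were set once to the scale of real stewardship data: count
intercept `log(0.9)` per DP-day and roughly half of stays antibiotic-free,
putting crude DOT near 480 per 1000 DP and (via `dasc_scale = 6.5`) DASC
near 3100 per 1000 DP; effect sizes for the handful of effect-bearing flags
are 0.15–0.5 on the log/logit scale. Because no external effect-size table
exists for these coefficients, they are testability choices, not estimates.

Two structural choices deserve note:

* **DOT and DASC share their zero event.** A stay with no antibiotic days
  has both metrics zero by definition, so the generator draws one
  structural-zero indicator (and shares zero-component intercepts) and
  couples the two count components only through a high intercept
  correlation (`dasc_intercept_cor`, default 0.9). Each outcome's marginal
  law remains exactly ZINB, so estimation truth is intact.
* **Case-mix confounding is a dial.** `case_mix_sd` shifts the logit
  prevalence of every effect-bearing flag by hospital severity
  $s_h \sim N(0,1)$; `severity_to_facility` controls how well the facility
  complexity attributes proxy that severity. `scenario_confounded()`
  freezes the configuration used for the ranking-pattern experiments:
  `case_mix_sd = 2.5` (case mix dominates the crude between-hospital
  spread), `severity_to_facility = 0.5` (complexity ratings are a weak
  proxy, as real ratings are), $\sigma_c = 0.2$, $\sigma_z = 0.3$,
  `dasc_intercept_cor = 0.95`, 60 hospitals of 500–700 stays.

What the generator does **not** emulate: real demographic composition,
within-stay administration timing, correlated flag structure (flags are
independent given severity), seasonal effects, or unit-level random
effects. Passing tests therefore demonstrate that the estimators recover
the structure they assume and rank hospitals correctly under controlled
confounding — not that any particular real dataset satisfies those
assumptions.

# Method 1 details and conventions

`fit_nb()` wraps the standard NB2 regression (`MASS::glm.nb`) on unit-month
aggregates; rate ratios are `exp(coef)` with Wald 95% CIs, reference levels
are the factors' first levels. Calendar month is not a model term.
Average-length-of-stay quintiles are computed on baseline records and the
cut points frozen for evaluation scoring (no leakage). O:E intervals treat
E as fixed and put an exact-Poisson interval on O — the usual
indirect-standardization convention, reported as such. Unseen factor levels
in evaluation data are an error, never silently re-referenced. Facility O:E
is observed over expected with expectations from fixed effects only.

# Ranking comparison

`kendall_tau_b()` implements the tie-corrected coefficient
$\tau_B = (C - D)/\sqrt{(n_0-n_1)(n_0-n_2)}$ directly (vectorized pair
counting; all-tied input is undefined and returns `NA` with a warning) and
is verified in the tests against an explicit pair-enumeration oracle and
`stats::cor`. τ is computed on the ratio/rate values themselves — identical
to computing it on ranks, since τ is invariant under strictly monotone
transforms. Strength labels: strong ≥ 0.7, moderate [0.5, 0.7), weak
< 0.5, with the boundary values classified upward. Ranks in the benchmark
table break ties by average rank, which is what makes the downstream tie
correction exact.

# Numerical choices and degenerate inputs

* Outer optimizer tolerances: `pgtol = 1e-6`, `factr = 1e7`; inner Newton
  stops at gradient sup-norm below `1e-8 (1 + |logpost|)` or 100
  iterations, with step halving.
* Non-PD inner curvature is ridged; if the curvature at the mode is still
  not PD the prior curvature bounds it (this occurs only in pathological
  flat regions, and then the Laplace value degrades gracefully toward the
  prior-only integral).
* Wald CIs come from the numerical Hessian of the Laplace objective at the
  optimum (`optimHess`); when it is singular the SEs are `NA` rather than
  fabricated.
* Constant covariates fail the prescreen rather than erroring; collinear
  terms in method 1 are dropped by the underlying QR with a warning.
* A hospital with no evaluation stays is omitted from BLUP re-estimation
  with a warning; a facility missing any benchmark column is flagged
  incomplete and dropped listwise from τ computations with a logged count.

# Problem sizes used in the shipped experiments

All simulations run on one CPU in minutes. Likelihood validation uses 6
hospitals × 30 stays; mixed-model recovery uses 10 replicates of 40
hospitals × 400 stays (σ_c = 0.3, σ_z = 0.4, θ = 1.5); unit-month NB
recovery uses 20 replicates of 2000 records; planted-effect benchmarking
uses 30 hospitals × 2000 stays; selection experiments use 10 hospitals ×
5000 stays (43 candidate flags) and, for the mediated-facility check, 10
replicates of 12 hospitals × 150 stays; the ranking-pattern experiment uses
`scenario_confounded()` at 60 hospitals. These sizes are far below a
multi-year national cohort; they were chosen so each estimator operates
comfortably above its small-sample breakdown while the full suite stays
desk-fast, and the acceptance checks state properties (coverage, ordering,
bands) rather than point reproductions of any published numbers.

# Known limitations

* The Laplace approximation's error grows for hospitals with very few
  stays and extreme zero fractions; the grid cross-check covers the scales
  used here, not all scales.
* ML (not REML) variance estimates are biased low with few hospitals;
  BLUP-based P:E inherits mild extra shrinkage there. This is visible in
  the planted-effect experiments and documented rather than corrected.
* The alternating penalized-ZINB selection is a working approximation to a
  joint penalized fit; it is used only to choose supports, never to report
  coefficients.
* DASC rounding, independence of flags given severity, and the absence of
  unit-level random effects are simplifications stated above.
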