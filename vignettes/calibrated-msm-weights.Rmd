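---
title: "Calibrated inverse probability weights for marginal structural models with irregular visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated inverse probability weights for marginal structural models with irregular visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmcal)
```

## The estimation problem

Longitudinal records from routine care are observed at visits that patients
and physicians choose, not at protocol times.  When the visit process, a
time-varying confounder and a time-varying treatment all feed back on one
another, three biases distort a regression of the outcome on treatment:
confounding by the time-dependent covariate, selection by the informative
visit process (outcomes are only recorded at visits), and — in the setting
this package targets — confounding by a subject-level latent trait that
influences both treatment uptake and the outcome.

`msmcal` estimates the parameters of a marginal structural model (MSM) for
a continuous outcome under an identity link,

$$E(Y_j^{\bar a,\bar v} \mid X) = \psi_0 + \psi_1 a_{j-1}
  [\; + \psi_2 v_{j-1}] + \psi' X,$$

by weighted generalized estimating equations, where the weights are
stabilized inverse-probability-of-treatment (IPT) and
inverse-probability-of-visit (IPV) weights, cumulated multiplicatively over
discrete time, and optionally *calibrated* by exponential tilting so that
the weighted sample satisfies exact finite-sample moment restrictions.

## The data-generating world

The synthetic-data module generates, per subject $i$ and interval
$j = 1..t$ (lagged values are 0 before the first interval):

* visit $V_j \sim \mathrm{Bern}(\mathrm{expit}(\omega_0 + \omega_1 L_{j-1}
  + \omega' X))$,
* outcome (drawn only at visits) $Y_j \sim N(\theta_0 + \theta_1 A_{j-1} +
  \theta_2 V_{j-1} + \theta_3 L_{j-1} + \theta' X + \theta_7\eta,\,
  \sigma^2_Y)$,
* confounder $L_j \sim \mathrm{Bern}(\mathrm{expit}(\mu_0 + \mu_1 V_{j-1}
  + \mu_2 Y_j + \mu_3 L_{j-1} + \mu_4 A_{j-1}))$,
* treatment $A_j \sim \mathrm{Bern}(\mathrm{expit}(\alpha_0 + \alpha_1
  V_{j-1} + \alpha_2 Y_j + \alpha_3 L_j + \alpha_4 A_{j-1} + \alpha' X +
  \alpha_8\eta))$,

with baseline covariates $X = (e^{U_1/2},\, U_1/(1+e^{U_2}),\, U_1U_3/25)$
from independent standard normals and $\eta_i \sim N(0,1)$ a time-invariant
latent confounder.  At a non-visit interval nothing is drawn: treatment and
confounder are carried forward and the outcome is missing.  The default
coefficients (see `scenario_config()`) put the visit probability near 1
(intercept 16) in "regular visit" scenarios and at $\mathrm{expit}(2 +
\ldots) \approx 0.88$ in irregular ones; the latent loadings
$\theta_7 = \alpha_8 = 0.1$ are active only in unmeasured-confounder
scenarios.

What a green test on this generator does *not* establish: the generator has
Bernoulli visits with a protocol-style history dependence, administrative
censoring only, a single binary confounder, and linear identity-link
outcome means.  Continuous-time visit intensities, informative dropout,
and outcome-model nonlinearity are outside the stated world, so estimator
performance there is not evidenced by these tests.

## Truth by G-computation

Because the outcome model is linear with identity link and no
interactions, the marginal effect of the lagged treatment is exactly
$\theta_1$ (`true_psi()`).  The package still carries the general Monte
Carlo G-computation path (`gcomp_marginal_mean()`, `gcomp_contrast()`):
draw $(\eta, X)$, then roll the confounder and outcome models forward with
the treatment and visit paths *set* to the intervened regimes, the outcome
drawn at every interval.  `gcomp_contrast(common_random = TRUE)` shares
all draws between the two arms, which for this linear mechanism removes
Monte Carlo noise from the contrast entirely; the independent-arm mode is
the honest stochastic oracle used in the acceptance report.

## Weights

Pooled logistic models produce the stabilized weights

$$SW^{A}_t = \prod_{j\le t}
  \frac{\Pr(A_j \mid \text{reduced history})}
       {\Pr(A_j \mid \text{full history})},\qquad
  SW^{V}_t \text{ analogously},$$

with the probability of the *observed* value in both numerator and
denominator, and joint weights as the cellwise product.  Two conventions
matter and are deliberate:

* **Treatment is modelled only at visits.**  Between visits the treatment
  is a deterministic carry-forward — its conditional probability is 1 in
  numerator and denominator, so those intervals contribute ratio 1.
  Pooling the deterministic rows into the logistic fit would inflate the
  lagged-treatment coefficient and contaminate the visit-interval
  propensities (measurably: the stabilized-IPT estimator then becomes
  *more* biased than the naive one in irregular-visit scenarios).
* **The lagged-history convention.**  The full-history conditioning sets
  follow the weight definition $\Pr(A_j\mid \bar H_{j-1})$ with strictly
  lagged history (previous visit, last outcome observed before the
  interval, lagged confounder, lagged treatment, baseline covariates) —
  see "Design choices" below.

`truncate_weights()` winsorizes pooled weights at sample quantiles (linear
interpolation, R type 7); the application-style pipeline truncates at
1%/99%, the scenario replication never truncates.

## Calibration by exponential tilting

A stabilized weight set $w$ is calibrated to $w\,e^{K\lambda}$, where the
columns of $K$ are the active moment restrictions and $\lambda$ solves

$$g(\lambda) = \textstyle\sum_{\text{cells}} w\, e^{K\lambda} K -
  \text{targets} = 0 .$$

Restriction families (per weight family, treatment and visit systems are
independent):

* **balance** — the weighted cumulative event residuals (event minus the
  stabilizing-model propensity) are orthogonal to a covariate basis.  The
  default basis is intercept + current + lagged confounder for the
  treatment family (the treatment drawn at an interval responds to the
  confounder drawn earlier in that same interval, so balancing against
  the current value targets exactly the under-adjustment the lagged
  propensity models leave), and intercept + lagged confounder for the
  visit family (the current confounder is realized after the visit
  indicator and must not be balanced against it);
* **unity** — the weights average to 1 at each interval, which anchors the
  solution and forbids the trivial collapse toward zero;
* **latent** — the weighted cumulative residuals sum to zero *within each
  interval*, absorbing the residual drift that a time-invariant
  subject-level confounder induces;
* **subject** — the hard per-subject version of the same restriction.

Because $g$ is the gradient of the strictly convex potential
$\Phi(\lambda) = \sum w e^{K\lambda} - t'\lambda$, the solver runs a
Barzilai–Borwein spectral gradient iteration with a non-monotone line
search, then a damped Newton tail with the analytic Hessian
$K' \mathrm{diag}(w e^{K\lambda}) K$ (tolerance $10^{-8}$ on the residual
max-norm; overall iteration budget 5000, BB phase capped at 300 since the
Newton tail converges quadratically once near the solution).  Redundant
columns are pruned before solving: the intercept balance column equals the
sum of the subject columns and also of the latent columns, and all-zero
columns are dropped.  Tilt exponents are clipped at $\pm 50$ *inside the
line search only*; a solution with any exponent at $+50$ is reported
non-converged.

**Boundary solutions.**  The per-subject family deserves a warning: a
subject whose cumulative residuals never change sign (an always-treated
subject, for instance) can satisfy its restriction only in the limit where
its weights vanish.  The solver then reports a vanishing residual while
the tilt diverges to $-\infty$ for those cells — roughly a quarter of
subjects in a typical replicate, which distorts the weight distribution
enough to double the Monte Carlo error of the downstream estimator.  The
per-interval **latent** family imposes the same cumulative-residual
balancing at the population level, admits interior solutions, leaves the
calibrated weights highly correlated with the stabilized ones, and is what
the scenario studies use for unmeasured-confounder scenarios.  Both
families are exported; the choice is a documented design decision, made
because the hard per-subject system is degenerate by construction on
binary treatment data.

## Weighted GEE

The MSM is fitted by Fisher scoring on the weighted GEE score with
identity link, AR(1) or independence working correlation, and robust
(sandwich) variance.  Prior weights follow the convention of the standard
GEE software this mirrors: $V_i = \phi\, W_i^{-1/2} R(\alpha)
W_i^{-1/2}$, so unit weights with independence reduce exactly to least
squares and the coefficients are invariant to rescaling all weights.
The AR(1) parameter is the weighted lag-1 moment estimator on
$\sqrt{w}$-scaled residuals over consecutive retained rows within a
cluster — a software convention, not a claim about the true correlation
structure.  Rows with a missing outcome are dropped.

**Fitting starts at interval 2.**  At interval 1 every lag is the virtual
pre-study zero, so interval-1 rows have a different mean level (through
$\theta_3 L_0$ and $\theta_2 V_0$) and a degenerate lagged treatment; a
pooled MSM without an interval term absorbs that offset into
$\hat\psi_1$.  No weighting can remove this — it is misspecification, not
confounding — and with interval-1 rows included even oracle-propensity
IPTW is off by +0.06 at $n = 50{,}000$.  The lagged-treatment MSM is
therefore fitted on intervals $j \ge 2$ (weight models still use the full
history from interval 1).

## Design choices made where the design was open

* **Full-history conditioning sets.**  The data-generating treatment model
  uses the *current* outcome and confounder; the weight definition
  conditions on history *through the previous interval*.  Both variants
  are implemented (`default_weight_specs()` vs. custom specs).  With
  current-information denominators the stabilized IPT estimator is already
  consistent and calibration has nothing left to correct — stabilized and
  calibrated estimators tie, which is not the behavior the method is
  meant to exhibit (nor what its reference results show).  The
  strictly-lagged convention leaves the finite-sample under-adjustment
  that calibration then visibly reduces, and is the default.
* **Bias sign convention.**  `summarize_estimates()` reports
  $\mathrm{bias} = \bar{\hat\psi} - \psi$, positive when attenuated toward
  zero from a negative truth, and relative bias against $|\psi|$.
* **Seeds.**  One seed per replicate (`base_seed + k`); estimators within
  a replicate share the panel, so comparisons are paired.  Results are
  invariant to the parallel worker count.

## Known limitations

* Robust sandwich variances ignore the estimation of the weights and of
  the calibration; with 100 clusters coverage sits one to two points
  below nominal, as expected for this variance estimator.
* The Monte Carlo errors of all estimators in this implementation are
  around 0.15 at $n = 100$ subjects and 10 intervals — the information
  content implied by the stated generating coefficients.  Reference
  results for this design report Monte Carlo errors near 0.30, which
  would require the treatment to be nearly subject-constant or an outcome
  standard deviation (not variance) of 3; neither matches the stated
  parameters, and we follow the parameters.
* Continuous-time visit intensities, informative censoring, doubly robust
  extensions and calibration-aware variance estimation are out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(4, seed = 1)      # irregular visits + latent confounder
set.seed(1)
panel <- simulate_panel(cfg)

tw <- stabilized_weights(panel, "treatment")
vw <- stabilized_weights(panel, "visit")
ct <- calibrate(tw, options = c("balance", "unity", "latent"))
cv <- calibrate(vw, options = c("balance", "unity", "latent"))

fit <- fit_weighted_gee(panel,
                        product_weights(list(ct$calibrated, cv$calibrated)),
                        msm_formula_terms(cfg), corr = "ar1",
                        min_interval = 2)
fit$beta[["a_lag"]]
wald_ci(fit, "a_lag")

## full scenario study (1000 replicates)
summary <- run_scenario(cfg, n_replicates = 1000, base_seed = 2000)
```
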