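# msmcal

Calibrated inverse probability weights for marginal structural models of
longitudinal outcomes observed at irregular visits, with an optional
subject-level unmeasured confounder.

## The problem

In routine-care longitudinal data (for example repeat HbA1c measurements
in primary-care records), three things bias a regression of an outcome on
a time-varying treatment:

1. **time-dependent confounding with feedback** — past treatment affects
   the current confounder, which affects future treatment;
2. **informative visits** — the outcome is only recorded when the patient
   shows up, and showing up depends on health history;
3. **subject-level latent confounding** — a stable unmeasured trait that
   drives both treatment uptake and the outcome.

`msmcal` estimates the parameters of a marginal structural model (MSM)

ψ(ā, v̄, X) = ψ₀ + ψ₁ a_{j−1} [+ ψ₂ v_{j−1}] + ψ' X

by weighted generalized estimating equations (identity link, AR(1)
working correlation, robust sandwich variance), where the weights are
stabilized inverse-probability-of-treatment (sIPTW) and
inverse-probability-of-visit (sIPVW) weights

SW_t = Π_{j≤t} Pr(event_j | reduced history) / Pr(event_j | full history),

optionally **calibrated** by exponential tilting w → w·exp(Kλ) so that
the weighted sample exactly satisfies covariate-balance, unity-mean and
latent-confounder moment restrictions, with λ solved by a
Barzilai–Borwein spectral iteration (Newton fallback) on a convex
potential.

The package also contains the discrete-time data-generating simulator
(Bernoulli visit/confounder/treatment processes with carry-forward
between visits and outcome masking), a Monte Carlo G-computation oracle
for the true marginal effect, and the orchestration of the four-scenario
Monte Carlo study (irregular visits × unmeasured confounder).

## Worked example

```r
library(msmcal)

cfg <- scenario_config(4, seed = 1)   # irregular visits + latent confounder
set.seed(1)
panel <- simulate_panel(cfg)
panel
#> <msm_panel> 100 subjects x 10 intervals; visit rate 0.888

tw <- stabilized_weights(panel, "treatment")
vw <- stabilized_weights(panel, "visit")
ct <- calibrate(tw, options = c("balance", "unity", "latent"))
cv <- calibrate(vw, options = c("balance", "unity", "latent"))
ct
#> <msm_calibration> 22 constraints; converged: TRUE; residual 4.26e-09; 70 iterations

fit <- fit_weighted_gee(panel,
                        product_weights(list(ct$calibrated, cv$calibrated)),
                        msm_formula_terms(cfg), corr = "ar1",
                        min_interval = 2)
fit$beta[["a_lag"]]                   # calibrated joint-weight estimate of psi1
#> [1] -0.3252707
wald_ci(fit, "a_lag")                 # robust 95% Wald interval
#>       lower       upper
#> -0.63773490 -0.01280641
true_psi(cfg)
#> [1] -0.3
```

A full scenario study (1000 replicates, ~2 min on one CPU):

```r
summary <- run_scenario(scenario_config(4), n_replicates = 1000, base_seed = 42)
summary[, c("estimator", "mean_estimate", "relative_bias_pct", "mce", "coverage")]
#>     estimator mean_estimate relative_bias_pct   mce coverage
#> 1       naive        -0.263              12.2 0.156    0.938
#> 2       sIPTW        -0.262              12.6 0.158    0.938
#> 3       sIPVW        -0.263              12.3 0.158    0.940
#> 4 sIPTWxsIPVW        -0.262              12.6 0.160    0.933
#> 5 cIPTWxcIPVW        -0.274               8.6 0.160    0.937
```

The truth is ψ₁ = −0.3; the naive and stabilized estimators are
attenuated, and the calibrated joint weights recover a substantial part
of the gap. Bias, Monte Carlo error, rMSE (= √(bias² + MCE²)), coverage
and convergence counts per estimator are the columns of the summary.

## Command line

```sh
Rscript inst/cli/msmcal.R simulate --scenario 3 --seed 1 --out panel.csv
Rscript inst/cli/msmcal.R run --scenario 1 --reps 1000 --seed 42 --out summary.csv
Rscript inst/cli/msmcal.R app-demo --n 2000 --seed 1
```

`simulate` writes a long-format CSV (id, interval, visit, treatment,
confounder, outcome with empty cells at missed visits, x1–x3); `run`
writes the per-estimator summary table; `app-demo` runs the
application-style pipeline — two prescription exposures, three calibrated
weight families multiplied and truncated at the 1%/99% quantiles, MSM on
cumulative prescription counts capped at two.

## Documentation

The methods vignette (`vignettes/calibrated-msm-weights.Rmd`) describes
the generating mechanism, the weight and calibration machinery, the
numerical choices (solver, tolerances, tie-breaks), the design decisions
taken where the design was open, and known limitations.
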