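#' Estimators and marginal-model terms for a scenario
#'
#' Scenarios without irregular visits compare the naive, stabilized-IPTW
#' and calibrated-IPTW estimators and exclude the lagged visit from the
#' marginal model; scenarios with irregular visits add the visit-weight
#' estimators and the lagged visit term.
#'
#' @param config an \code{msm_scenario}.
#' @return character vector of estimator names.
#' @export
default_estimators <- function(config) {
  if (config$irregular_visits)
    c("naive", "sIPTW", "sIPVW", "sIPTWxsIPVW", "cIPTWxcIPVW")
  else
    c("naive", "sIPTW", "cIPTW")
}

#' @rdname default_estimators
#' @export
msm_formula_terms <- function(config) {
  if (config$irregular_visits) c("a_lag", "v_lag", "x1", "x2", "x3")
  else c("a_lag", "x1", "x2", "x3")
}

all_estimators <- c("naive", "sIPTW", "sIPVW", "sIPTWxsIPVW",
                    "cIPTW", "cIPVW", "cIPTWxcIPVW")

#' Run one simulation replicate
#'
#' Simulates one panel under the scenario, builds every weight family the
#' requested estimators need (stabilized treatment/visit weights; their
#' calibrated versions with balance + unity restrictions, plus the
#' per-subject latent restrictions when the scenario has an unmeasured
#' confounder), fits the scenario's marginal structural model by weighted
#' GEE with AR(1) working correlation, and returns the lagged-treatment
#' coefficient with its robust Wald interval per estimator.
#'
#' @param config an \code{msm_scenario}.
#' @param estimators subset of
#'   \code{naive, sIPTW, sIPVW, sIPTWxsIPVW, cIPTW, cIPVW, cIPTWxcIPVW}.
#' @param seed integer seed for this replicate.
#' @param specs numerator/denominator regressor sets per weight family, in
#'   the shape of [default_weight_specs()].
#' @return data.frame with one row per estimator: \code{estimator},
#'   \code{estimate}, \code{lower}, \code{upper}, \code{converged}.
#' @export
run_replicate <- function(config, estimators = default_estimators(config),
                          seed = config$seed,
                          specs = default_weight_specs()) {
  stopifnot(inherits(config, "msm_scenario"))
  estimators <- match.arg(estimators, all_estimators, several.ok = TRUE)
  visit_based <- c("sIPVW", "sIPTWxsIPVW", "cIPVW", "cIPTWxcIPVW")
  if (!config$irregular_visits && any(estimators %in% visit_based))
    stop("visit-weight estimators require irregular visits", call. = FALSE)
  set.seed(seed)
  panel <- simulate_panel(config)
  cal_opts <- c("balance", "unity",
                if (config$unmeasured_confounder) "latent")

  need_tw <- any(estimators %in% c("sIPTW", "sIPTWxsIPVW", "cIPTW",
                                   "cIPTWxcIPVW"))
  need_vw <- any(estimators %in% visit_based)
  tw <- if (need_tw) stabilized_weights(panel, "treatment",
                                        specs$treatment$num,
                                        specs$treatment$den)
  vw <- if (need_vw) stabilized_weights(panel, "visit",
                                        specs$visit$num, specs$visit$den)
  ct <- if (any(estimators %in% c("cIPTW", "cIPTWxcIPVW")))
    calibrate(tw, options = cal_opts)
  cv <- if (any(estimators %in% c("cIPVW", "cIPTWxcIPVW")))
    calibrate(vw, options = cal_opts)

  pick <- function(est) {
    switch(est,
           naive = list(w = unit_weights(panel), ok = TRUE),
           sIPTW = list(w = tw, ok = tw$numerator_fit$converged &&
                          tw$denominator_fit$converged),
           sIPVW = list(w = vw, ok = vw$numerator_fit$converged &&
                          vw$denominator_fit$converged),
           sIPTWxsIPVW = list(
             w = product_weights(list(tw, vw)),
             ok = tw$numerator_fit$converged && tw$denominator_fit$converged &&
               vw$numerator_fit$converged && vw$denominator_fit$converged),
           cIPTW = list(w = ct$calibrated, ok = ct$converged),
           cIPVW = list(w = cv$calibrated, ok = cv$converged),
           cIPTWxcIPVW = list(
             w = product_weights(list(ct$calibrated, cv$calibrated)),
             ok = ct$converged && cv$converged))
  }
  terms <- msm_formula_terms(config)
  rows <- lapply(estimators, function(est) {
    sel <- pick(est)
    fit <- fit_weighted_gee(panel, sel$w, terms, corr = "ar1",
                            min_interval = 2L)
    ci <- wald_ci(fit, "a_lag")
    data.frame(estimator = est, estimate = unname(fit$beta[["a_lag"]]),
               lower = unname(ci[1]), upper = unname(ci[2]),
               converged = sel$ok && fit$converged)
  })
  out <- do.call(rbind, rows)
  out$seed <- seed
  out
}

#' Summarize replicate estimates into performance metrics
#'
#' Computes the Monte Carlo performance metrics of an estimator against
#' the true marginal effect: \code{bias = mean(estimate) - psi_true}
#' (positive when the estimate is attenuated toward zero from a negative
#' truth), relative bias as a percentage of \code{|psi_true|}, Monte Carlo
#' error (SD of the estimates), \code{rmse = sqrt(bias^2 + mce^2)}, and
#' coverage of the confidence intervals.
#'
#' @param estimates numeric vector of per-replicate estimates (converged
#'   replicates only).
#' @param true_psi true marginal effect.
#' @param lower,upper optional CI bounds aligned with \code{estimates};
#'   coverage is \code{NA} if omitted.
#' @param n_replicates total replicates attempted (defaults to
#'   \code{length(estimates)}).
#' @return one-row data.frame with the metric columns.
#' @export
summarize_estimates <- function(estimates, true_psi, lower = NULL,
                                upper = NULL,
                                n_replicates = length(estimates)) {
  if (length(estimates) < 2)
    stop("need at least 2 converged replicates", call. = FALSE)
  bias <- mean(estimates) - true_psi
  mce <- stats::sd(estimates)
  coverage <- if (is.null(lower) || is.null(upper)) NA_real_
  else mean(lower <= true_psi & true_psi <= upper)
  data.frame(psi_true = true_psi,
             mean_estimate = mean(estimates),
             bias = bias,
             relative_bias_pct = 100 * bias / abs(true_psi),
             mce = mce,
             rmse = sqrt(bias^2 + mce^2),
             coverage = coverage,
             n_converged = length(estimates),
             n_replicates = n_replicates)
}

#' Run a full scenario Monte Carlo study
#'
#' Repeats [run_replicate()] with per-replicate seeds derived
#' deterministically from \code{base_seed} (seed + replicate index), drops
#' non-converged replicates per estimator (reporting the counts), and
#' summarizes each estimator with [summarize_estimates()] against the
#' G-computation truth \code{true_psi(config)}.
#'
#' @param config an \code{msm_scenario}.
#' @param n_replicates number of replicates (>= 2).
#' @param base_seed integer; replicate k uses seed \code{base_seed + k}.
#' @param estimators estimator names; default per scenario.
#' @param specs weight-model regressor sets, as in [run_replicate()].
#' @param jobs parallel workers over replicates (forked; results are
#'   identical for any worker count because seeds are per-replicate).
#' @return data.frame with one row per estimator (the scenario summary
#'   table), with attribute \code{"replicates"} holding the per-replicate
#'   results.
#' @export
run_scenario <- function(config, n_replicates = config$n_replicates,
                         base_seed = config$seed,
                         estimators = default_estimators(config),
                         specs = default_weight_specs(),
                         jobs = 1L) {
  stopifnot(n_replicates >= 2)
  seeds <- base_seed + seq_len(n_replicates)
  stopifnot(max(seeds) < 2^31)
  one <- function(s) run_replicate(config, estimators, seed = s,
                                   specs = specs)
  reps <- if (jobs > 1 && .Platform$OS.type == "unix")
    parallel::mclapply(seeds, one, mc.cores = jobs)
  else lapply(seeds, one)
  reps <- do.call(rbind, reps)
  psi <- true_psi(config)
  out <- do.call(rbind, lapply(estimators, function(est) {
    sub <- reps[reps$estimator == est, ]
    ok <- sub[sub$converged, ]
    s <- summarize_estimates(ok$estimate, psi, ok$lower, ok$upper,
                             n_replicates = nrow(sub))
    cbind(data.frame(estimator = est, effect = "a_lag"), s)
  }))
  attr(out, "replicates") <- reps
  out
}

#' Simulate a two-exposure panel for the application-style pipeline
#'
#' A synthetic stand-in for an EHR cohort with two concurrent binary
#' prescription exposures, irregular visits and a continuous longitudinal
#' marker.  The outcome responds to each exposure through the cumulative
#' number of prescribed intervals capped at two (the coding the analysis
#' model uses), so the analysis coefficients are directly the generating
#' effects.
#'
#' @param n subjects.
#' @param t intervals.
#' @param effects length-2 numeric: per-unit effects of the two capped
#'   cumulative exposures.
#' @return an \code{msm_panel} with an extra binary matrix \code{A2}.
#' @export
simulate_two_exposure_panel <- function(n, t = 10L,
                                        effects = c(-0.4, -0.3)) {
  X <- draw_baseline_covariates(n)
  xb_v <- 0.1 * (X[, 1] + X[, 2] + X[, 3])
  xb_a <- 0.3 * X[, 1] + 0.3 * X[, 2] + 0.6 * X[, 3]
  xb_y <- 0.5 * (X[, 1] + X[, 2] + X[, 3])
  V <- A <- A2 <- L <- matrix(0L, n, t)
  Y <- matrix(NA_real_, n, t)
  v_prev <- a_prev <- a2_prev <- l_prev <- integer(n)
  cc1 <- cc2 <- numeric(n)  # capped cumulative exposures through j-1
  for (j in seq_len(t)) {
    vj <- as.integer(stats::runif(n) < expit(2 + 0.1 * l_prev + xb_v))
    idx <- which(vj == 1L)
    aj <- a_prev; a2j <- a2_prev; lj <- l_prev
    if (length(idx)) {
      yj <- stats::rnorm(length(idx),
                         mean = 9 + effects[1] * cc1[idx] +
                           effects[2] * cc2[idx] - 0.1 * v_prev[idx] +
                           0.5 * l_prev[idx] + xb_y[idx],
                         sd = sqrt(3))
      Y[idx, j] <- yj
      pl <- expit(0.1 * v_prev[idx] + 0.1 * a_prev[idx] +
                    0.1 * a2_prev[idx])
      lj[idx] <- as.integer(stats::runif(length(idx)) < pl)
      pa <- expit(-0.5 + 0.1 * v_prev[idx] + 0.1 * lj[idx] + xb_a[idx])
      aj[idx] <- as.integer(stats::runif(length(idx)) < pa)
      pa2 <- expit(-0.5 + 0.1 * v_prev[idx] + 0.1 * lj[idx] - xb_a[idx])
      a2j[idx] <- as.integer(stats::runif(length(idx)) < pa2)
    }
    V[, j] <- vj; A[, j] <- aj; A2[, j] <- a2j; L[, j] <- lj
    cc1 <- pmin(cc1 + aj, 2); cc2 <- pmin(cc2 + a2j, 2)
    v_prev <- vj; a_prev <- aj; a2_prev <- a2j; l_prev <- lj
  }
  structure(list(V = V, A = A, A2 = A2, L = L, Y_latent = Y, Y_obs = Y,
                 X = X, eta = rep(0, n), config = NULL),
            class = "msm_panel")
}

#' Application-style multi-exposure weighted analysis
#'
#' Mirrors a target-trial analysis with two prescription exposures and
#' irregular visits: builds stabilized weight families for each exposure
#' and for the visit process, calibrates each (balance + unity), takes the
#' cellwise product, truncates at the 1\%/99\% pooled quantiles, and fits
#' the marginal model for the outcome on the two capped cumulative
#' exposures, the lagged visit, and baseline covariates.  An exposure with
#' no variation gets a unit weight family (degenerate-fit fallback).
#'
#' @param panel an \code{msm_panel} carrying \code{A2} (see
#'   [simulate_two_exposure_panel()]).
#' @param truncate_q length-2 quantile probabilities for weight
#'   truncation.
#' @return an \code{msm_gee} fit, with the weight set attached as
#'   attribute \code{"weights"}.
#' @export
run_application_pipeline <- function(panel, truncate_q = c(0.01, 0.99)) {
  stopifnot(inherits(panel, "msm_panel"), !is.null(panel$A2))
  exposure_weights <- function(p) {
    tryCatch(calibrate(stabilized_weights(p, "treatment"),
                       options = c("balance", "unity"))$calibrated,
             error = function(e) unit_weights(p))
  }
  w1 <- exposure_weights(panel)
  panel2 <- panel; panel2$A <- panel$A2
  w2 <- exposure_weights(panel2)
  wv <- tryCatch(calibrate(stabilized_weights(panel, "visit"),
                           options = c("balance", "unity"))$calibrated,
                 error = function(e) unit_weights(panel))
  w1$panel <- w2$panel <- wv$panel <- panel
  raw <- product_weights(list(w1, w2, wv))
  w <- truncate_weights(raw, truncate_q[1], truncate_q[2])
  terms <- c(if (length(unique(as.vector(panel$A))) > 1) "cc_a_lag",
             if (length(unique(as.vector(panel$A2))) > 1) "cc_a2_lag",
             "v_lag", "x1", "x2", "x3")
  fit <- fit_weighted_gee(panel, w, terms, corr = "ar1", min_interval = 2L)
  attr(fit, "weights") <- w
  attr(fit, "weights_raw") <- raw
  attr(fit, "weight_families") <- list(exposure1 = w1, exposure2 = w2,
                                       visit = wv)
  fit
}
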