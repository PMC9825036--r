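test_that("unit weights with independence reproduce least squares", {
  p <- scenario_panel(3, n = 80, t = 8, seed = 41)
  terms <- c("a_lag", "v_lag", "x1", "x2", "x3")
  fit <- fit_weighted_gee(p, unit_weights(p), terms, corr = "independence")
  df <- data.frame(y = as.numeric(p$Y_obs), panel_design(p, terms))
  ref <- lm(y ~ ., data = df[!is.na(df$y), ])
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("beta is invariant to rescaling the weights", {
  p <- scenario_panel(4, n = 60, t = 8, seed = 42)
  tw <- stabilized_weights(p, "treatment")
  terms <- msm_formula_terms(p_config <- scenario_config(4))
  f1 <- fit_weighted_gee(p, tw, terms, corr = "ar1")
  tw7 <- tw; tw7$sw <- tw$sw * 7
  f2 <- fit_weighted_gee(p, tw7, terms, corr = "ar1")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-10)
})

test_that("one observation per cluster makes AR(1) and independence agree", {
  cfg <- scenario_config(1, n_subjects = 60, n_intervals = 1)
  set.seed(43)
  p <- simulate_panel(cfg)
  f_ar <- fit_weighted_gee(p, unit_weights(p), c("x1", "x2"), corr = "ar1")
  f_in <- fit_weighted_gee(p, unit_weights(p), c("x1", "x2"),
                           corr = "independence")
  expect_equal(f_ar$beta, f_in$beta, tolerance = 1e-10)
  expect_equal(f_ar$robust_se, f_in$robust_se, tolerance = 1e-10)
})

test_that("duplicating every cluster shrinks robust SEs by sqrt(2)", {
  p <- scenario_panel(1, n = 50, t = 6, seed = 44)
  dup <- p
  for (nm in c("V", "A", "L", "Y_latent", "Y_obs"))
    dup[[nm]] <- rbind(p[[nm]], p[[nm]])
  dup$X <- rbind(p$X, p$X); dup$eta <- c(p$eta, p$eta)
  terms <- c("a_lag", "x1", "x2", "x3")
  f1 <- fit_weighted_gee(p, unit_weights(p), terms, corr = "independence")
  f2 <- fit_weighted_gee(dup, unit_weights(dup), terms,
                         corr = "independence")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f2$robust_se, f1$robust_se / sqrt(2), tolerance = 1e-10)
  # AR(1) version agrees approximately (moment-estimator denominators)
  g1 <- fit_weighted_gee(p, unit_weights(p), terms, corr = "ar1")
  g2 <- fit_weighted_gee(dup, unit_weights(dup), terms, corr = "ar1")
  expect_equal(g2$robust_se, g1$robust_se / sqrt(2), tolerance = 0.02)
})

test_that("stored 20-cluster fixture matches the reference implementation", {
  panel_path <- system.file("extdata", "gee_reference_panel.csv",
                            package = "msmcal")
  expected <- jsonlite::read_json(
    system.file("extdata", "gee_reference_expected.json",
                package = "msmcal"), simplifyVector = TRUE)
  p <- read_panel_csv(panel_path)
  fit <- fit_weighted_gee(p, unit_weights(p),
                          c("a_lag", "v_lag", "x1", "x2", "x3"),
                          corr = "independence")
  expect_equal(unname(fit$beta), expected$beta, tolerance = 1e-4)
  expect_equal(unname(fit$robust_se), expected$robust_se, tolerance = 1e-4)
})

test_that("min_interval drops early rows from the outcome regression only", {
  p <- scenario_panel(1, n = 50, t = 6, seed = 45)
  q <- p
  q$Y_obs[, 1] <- q$Y_obs[, 1] + 100  # perturb interval-1 outcomes
  terms <- c("a_lag", "x1", "x2", "x3")
  f_p <- fit_weighted_gee(p, unit_weights(p), terms, corr = "ar1",
                          min_interval = 2)
  f_q <- fit_weighted_gee(q, unit_weights(q), terms, corr = "ar1",
                          min_interval = 2)
  expect_equal(f_p$beta, f_q$beta, tolerance = 1e-12)
})

test_that("Wald intervals and input validation behave", {
  fit <- structure(list(beta = c(a_lag = -0.3),
                        robust_se = c(a_lag = 0.1),
                        robust_cov = matrix(0.01, 1, 1,
                                            dimnames = list("a_lag", "a_lag"))),
                   class = "msm_gee")
  ci <- wald_ci(fit, "a_lag", 0.95)
  expect_equal(unname(ci), c(-0.3 - 1.959964 * 0.1, -0.3 + 1.959964 * 0.1),
               tolerance = 1e-6)
  fit0 <- structure(list(beta = c(a_lag = -0.3),
                         robust_se = c(a_lag = 0)), class = "msm_gee")
  expect_equal(unname(wald_ci(fit0, "a_lag")), c(-0.3, -0.3))
  expect_error(wald_ci(fit, "nope"), "unknown coefficient")
  p <- scenario_panel(1, n = 1, t = 4, seed = 46)
  expect_error(fit_weighted_gee(p, unit_weights(p), "x1"),
               "at least 2 clusters")
})
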