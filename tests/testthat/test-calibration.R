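test_that("balance columns are cumulative inner sums", {
  p <- make_panel(matrix(1L, 1, 2))
  res <- matrix(c(0.5, -0.5), 1, 2)
  K <- build_balance_constraints(p, res,
                                 covariate_basis = list(
                                   intercept = matrix(1, 1, 2)))
  expect_equal(as.numeric(K), c(0.5, 0.0))

  # zero residuals give vacuous columns and lambda = 0 is a root
  K0 <- build_balance_constraints(p, matrix(0, 1, 2))
  expect_true(all(K0 == 0))
})

test_that("subject columns sum to the intercept balance column", {
  p <- scenario_panel(2, n = 50, t = 8, seed = 31)
  tw <- stabilized_weights(p, "treatment")
  res <- (p$A - tw$numerator_fit$fitted) * tw$numerator_fit$cells
  Ks <- build_subject_constraints(p, res)
  Kl <- build_latent_constraints(p, res)
  Kb <- build_balance_constraints(p, res)
  expect_equal(rowSums(Ks), unname(Kb[, "intercept"]), tolerance = 1e-12)
  expect_equal(rowSums(Kl), unname(Kb[, "intercept"]), tolerance = 1e-12)
})

test_that("single-unity-constraint toy has the closed-form solution", {
  base <- make_weights(matrix(c(2, 0.5), 2, 1))
  u <- build_unity_constraints(2, 1)
  sys <- new_constraint_system(base, u$K, u$targets)
  out <- solve_lambda(sys, tol = 1e-10)
  expect_true(out$converged)
  expect_equal(unname(out$lambda), log(0.8), tolerance = 1e-8)
  expect_equal(as.numeric(out$calibrated$sw), c(2, 0.5) * 0.8,
               tolerance = 1e-8)
})

test_that("lambda = 0 on an empty system reproduces base weights bit-exactly", {
  p <- scenario_panel(1, n = 20, t = 4, seed = 32)
  tw <- stabilized_weights(p, "treatment")
  sys <- new_constraint_system(tw, matrix(0, 80, 2), c(0, 0))
  out <- solve_lambda(sys)
  expect_true(out$converged)
  expect_identical(out$calibrated$sw, tw$sw)
  expect_identical(out$lambda, c(0, 0))
})

test_that("balance + unity calibration satisfies its contracts", {
  p <- scenario_panel(1, seed = 33)
  tw <- stabilized_weights(p, "treatment")
  out <- calibrate(tw, options = c("balance", "unity"))
  expect_true(out$converged)
  # independent recomputation, not solver internals
  expect_lt(max(abs(calibration_residuals(out))), 1e-6)
  expect_true(all(abs(colMeans(out$calibrated$sw) - 1) <= 1e-6))
  expect_true(all(out$calibrated$sw > 0))
  # association with the stabilized weights (loose stochastic check):
  # substantial under the default current+lagged balance basis, and near
  # identity under the gentler lagged-only basis
  expect_gt(cor(as.vector(tw$sw), as.vector(out$calibrated$sw)), 0.5)
  n <- nrow(p$V); tt <- ncol(p$V)
  out_lag <- calibrate(tw, options = c("balance", "unity"),
                       covariate_basis = list(
                         intercept = matrix(1, n, tt),
                         l_lag = matrix(panel_design(p, "l_lag"), n, tt)))
  expect_true(out_lag$converged)
  expect_gt(cor(as.vector(tw$sw), as.vector(out_lag$calibrated$sw)), 0.9)
})

test_that("latent per-interval restrictions are satisfied when active", {
  p <- scenario_panel(2, seed = 34)
  tw <- stabilized_weights(p, "treatment")
  out <- calibrate(tw, options = c("balance", "unity", "latent"))
  expect_true(out$converged)
  expect_lt(max(abs(calibration_residuals(out))), 1e-6)
  res <- (p$A - tw$numerator_fit$fitted) * tw$numerator_fit$cells
  cum <- t(apply(res, 1, cumsum))
  for (j in seq_len(ncol(p$V)))
    expect_lt(abs(sum(out$calibrated$sw[, j] * cum[, j])), 1e-6)
})

test_that("hard per-subject restrictions drive per-subject sums to zero", {
  p <- scenario_panel(2, n = 60, t = 8, seed = 35)
  tw <- stabilized_weights(p, "treatment")
  out <- calibrate(tw, options = c("balance", "unity", "subject"))
  expect_lt(out$residual_norm, 1e-6)
  res <- (p$A - tw$numerator_fit$fitted) * tw$numerator_fit$cells
  cum <- t(apply(res, 1, cumsum))
  subj_sums <- rowSums(out$calibrated$sw * cum)
  expect_lt(max(abs(subj_sums)), 1e-6)
  expect_true(all(out$calibrated$sw >= 0))
})

test_that("calibration report summarizes families and residual norms", {
  p <- scenario_panel(2, n = 40, t = 6, seed = 37)
  tw <- stabilized_weights(p, "treatment")
  out <- calibrate(tw, options = c("balance", "unity", "latent"))
  path <- tempfile(fileext = ".json")
  rep <- calibration_report(out, path)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$residual_norm_after, out$residual_norm,
               tolerance = 1e-12)
  expect_gt(rep$residual_norm_before, rep$residual_norm_after)
  expect_setequal(names(rep$constraints), c("balance", "unity", "latent"))
  unlink(path)
})

test_that("visit-weight calibration is an independent system", {
  p <- scenario_panel(3, seed = 36)
  vw <- stabilized_weights(p, "visit")
  out <- calibrate(vw, options = c("balance", "unity"))
  expect_true(out$converged)
  expect_lt(max(abs(calibration_residuals(out))), 1e-6)
  expect_true(all(abs(colMeans(out$calibrated$sw) - 1) <= 1e-6))
})
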