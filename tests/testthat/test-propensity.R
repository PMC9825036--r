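test_that("intercept-only pooled fit recovers the Bernoulli MLE", {
  V <- matrix(1L, 10, 10)
  A <- matrix(0L, 10, 10); A[1:8, ] <- 1L  # event fraction 0.8
  p <- make_panel(V, A = A)
  fit <- fit_pooled_logistic(p, "treatment", character(0))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               qlogis(0.8), tolerance = 1e-7)
  expect_lt(fit$score_max, 1e-6)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("pooled logistic agrees with glm and recovers the DGM", {
  # oracle equivalence on a small panel against base glm
  p <- scenario_panel(3, n = 50, t = 4, seed = 21)
  spec <- c("v_lag", "a_lag", "x1", "x2", "x3")
  fit <- fit_pooled_logistic(p, "visit", spec)
  df <- data.frame(y = as.numeric(p$V), panel_design(p, spec))
  ref <- glm(y ~ ., data = df, family = binomial(),
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)

  # coefficient recovery at n*t = 1e5 within 3 SE (information-based)
  cfg <- scenario_config(1, n_subjects = 10000)
  set.seed(22)
  big <- simulate_panel(cfg)
  den_spec <- c("v_lag", "last_y_incl", "l_cur", "a_lag", "x1", "x2", "x3")
  dfit <- fit_pooled_logistic(big, "treatment", den_spec)
  truth <- c(cfg$alpha[1], cfg$alpha[2], cfg$alpha[3], cfg$alpha[4],
             cfg$alpha[5], cfg$alpha[6], cfg$alpha[7], cfg$alpha[8])
  Xd <- cbind(1, panel_design(big, den_spec))
  pr <- as.numeric(dfit$fitted)
  se <- sqrt(diag(solve(crossprod(Xd, Xd * (pr * (1 - pr))))))
  expect_true(all(abs(dfit$coefficients - truth) < 3 * se))
})

test_that("perfect separation is flagged and constants are errors", {
  V <- matrix(1L, 2, 2)
  A <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  L <- A  # l_cur perfectly predicts the event
  p <- make_panel(V, A = A, L = L)
  fit <- fit_pooled_logistic(p, "treatment", "l_cur")
  expect_false(fit$converged)

  p0 <- make_panel(V, A = matrix(1L, 2, 2))
  expect_error(fit_pooled_logistic(p0, "treatment", "l_cur"), "degenerate")
})

test_that("stabilized weights telescope and match a hand computation", {
  p <- scenario_panel(1, n = 40, t = 5, seed = 23)
  spec <- c("v_lag", "a_lag", "x1")
  # numerator = denominator -> all weights exactly 1
  w_id <- stabilized_weights(p, "treatment", spec, spec)
  expect_equal(max(abs(w_id$sw - 1)), 0, tolerance = 1e-12)

  # hand-computed oracle via glm fits on visit cells
  w <- stabilized_weights(p, "treatment",
                          numerator_spec = c("a_lag", "x1"),
                          denominator_spec = c("a_lag", "l_cur", "x1"))
  cells <- p$V == 1
  hand_fit <- function(terms) {
    df <- data.frame(y = as.numeric(p$A), panel_design(p, terms))
    g <- glm(y ~ ., data = df[as.vector(cells), , drop = FALSE],
             family = binomial(), control = glm.control(epsilon = 1e-12))
    pr <- predict(g, newdata = df, type = "response")
    matrix(ifelse(df$y == 1, pr, 1 - pr), nrow(p$V))
  }
  ratio <- hand_fit(c("a_lag", "x1")) / hand_fit(c("a_lag", "l_cur", "x1"))
  ratio[!cells] <- 1
  expect_equal(w$sw, t(apply(ratio, 1, cumprod)), tolerance = 1e-8)

  # telescoping: sw_t = sw_{t-1} * interval ratio
  expect_equal(w$sw[, 5] / w$sw[, 4], ratio[, 5], tolerance = 1e-10)
  expect_true(all(w$sw > 0))
})

test_that("product weights form a commutative monoid with unit identity", {
  p <- scenario_panel(3, n = 30, t = 4, seed = 24)
  tw <- stabilized_weights(p, "treatment")
  vw <- stabilized_weights(p, "visit")
  ones <- unit_weights(p)
  expect_equal(product_weights(list(ones, tw))$sw, tw$sw)
  expect_equal(product_weights(list(tw, vw))$sw,
               product_weights(list(vw, tw))$sw)
  w3 <- product_weights(list(make_weights(matrix(2, 2, 2)),
                             make_weights(matrix(0.5, 2, 2)),
                             make_weights(matrix(3, 2, 2))))
  expect_equal(w3$sw, matrix(3, 2, 2))
  expect_error(product_weights(list(tw, make_weights(matrix(1, 2, 2)))),
               "aligned")
})

test_that("weight truncation follows the linear-interpolation quantile", {
  w <- make_weights(matrix(1:100, 10, 10))
  tr <- truncate_weights(w, 0.01, 0.99)
  expect_equal(min(tr$sw), 1.99)
  expect_equal(max(tr$sw), 99.01)
  expect_equal(truncate_weights(w, 0, 1)$sw, w$sw)
  wc <- make_weights(matrix(2, 3, 3))
  expect_equal(truncate_weights(wc, 0.01, 0.99)$sw, wc$sw)
  expect_error(truncate_weights(w, 0.5, 0.5), "lower_q < upper_q")
})

test_that("weights export to long CSV", {
  p <- scenario_panel(1, n = 5, t = 3, seed = 27)
  tw <- stabilized_weights(p, "treatment")
  path <- tempfile(fileext = ".csv")
  write_weights_csv(tw, path)
  back <- read.csv(path)
  expect_equal(names(back), c("id", "interval", "weight", "kind"))
  expect_equal(nrow(back), 15)
  m <- matrix(NA_real_, 5, 3)
  m[cbind(back$id, back$interval)] <- back$weight
  expect_equal(m, tw$sw, tolerance = 1e-12)
  expect_true(all(back$kind == "treatment"))
  unlink(path)
})

test_that("stabilized weights have mean near one at each interval", {
  p_small <- scenario_panel(1, n = 100, t = 10, seed = 25)
  tw_small <- stabilized_weights(p_small, "treatment")
  expect_true(all(abs(colMeans(tw_small$sw) - 1) <= 0.25))

  p_big <- scenario_panel(1, n = 5000, t = 10, seed = 26)
  tw_big <- stabilized_weights(p_big, "treatment")
  expect_true(all(abs(colMeans(tw_big$sw) - 1) <= 0.05))
})
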