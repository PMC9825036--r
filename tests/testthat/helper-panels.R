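# build a minimal msm_panel from explicit matrices (tests only)
make_panel <- function(V, A = NULL, L = NULL, Y = NULL, X = NULL) {
  V <- as.matrix(V)
  n <- nrow(V); t <- ncol(V)
  if (is.null(A)) A <- matrix(0L, n, t)
  if (is.null(L)) L <- matrix(0L, n, t)
  if (is.null(Y)) { Y <- matrix(9, n, t); Y[V == 0] <- NA }
  if (is.null(X)) X <- matrix(0, n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  structure(list(V = V, A = as.matrix(A), L = as.matrix(L),
                 Y_latent = Y, Y_obs = Y, X = X,
                 eta = rep(0, n), config = NULL),
            class = "msm_panel")
}

# weight set with explicit weights, for truncation/product tests
make_weights <- function(sw, kind = "unit") {
  structure(list(sw = as.matrix(sw), kind = kind, numerator_fit = NULL,
                 denominator_fit = NULL, panel = NULL),
            class = "msm_weights")
}

scenario_panel <- function(scenario, n = 100, t = 10, seed = 1) {
  cfg <- scenario_config(scenario, n_subjects = n, n_intervals = t)
  set.seed(seed)
  simulate_panel(cfg)
}
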