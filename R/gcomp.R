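#' Monte Carlo G-computation of marginal potential-outcome means
#'
#' Computes \eqn{E(Y_j^{\bar a, \bar v})} for a deterministic treatment
#' regime \eqn{\bar a} and visit regime \eqn{\bar v} by forward simulation
#' of the data-generating mechanism with the treatment and visit equations
#' replaced by the intervened paths.  The latent confounder \eqn{\eta}, the
#' baseline covariates, the confounder path and the outcome path are drawn
#' from their models at every interval (under intervention the outcome is
#' defined at every interval; intervening on the visit sets the value the
#' downstream models see, it does not mask the outcome).  Because the
#' outcome model is linear with the identity link and no interactions, the
#' marginal contrast in the lagged treatment equals \eqn{\theta_1}; the
#' Monte Carlo path is the independent check of that closed form.
#'
#' @param config an \code{msm_scenario}.
#' @param a_bar,v_bar binary vectors of length \code{config$n_intervals}:
#'   the intervened treatment and visit paths.
#' @param j interval at which the mean potential outcome is evaluated.
#' @param n_mc Monte Carlo sample size.
#' @return a list with \code{mean}, \code{se} (Monte Carlo standard error)
#'   and \code{n_mc}.
#' @export
gcomp_marginal_mean <- function(config, a_bar, v_bar, j, n_mc = 1e5) {
  stopifnot(inherits(config, "msm_scenario"))
  t <- config$n_intervals
  if (length(a_bar) != t || length(v_bar) != t)
    stop("intervened paths must have length n_intervals", call. = FALSE)
  if (!all(a_bar %in% c(0, 1)) || !all(v_bar %in% c(0, 1)))
    stop("intervened paths must be binary", call. = FALSE)
  if (j < 1 || j > t) stop("j must lie in 1..n_intervals", call. = FALSE)
  if (n_mc < 1) stop("n_mc must be >= 1", call. = FALSE)

  y <- gcomp_draw_y(config, a_bar, v_bar, j, n_mc)
  list(mean = mean(y), se = stats::sd(y) / sqrt(n_mc), n_mc = n_mc)
}

# Forward-simulates n_mc independent (eta, X, L-path, Y-path) trajectories
# under the intervened (a_bar, v_bar) and returns the interval-j outcomes.
gcomp_draw_y <- function(config, a_bar, v_bar, j, n_mc) {
  th <- config$theta; mu <- config$mu; sd_y <- sqrt(config$sigma2_y)
  eta <- stats::rnorm(n_mc)
  X <- draw_baseline_covariates(n_mc)
  xb_y <- th[5] * X[, 1] + th[6] * X[, 2] + th[7] * X[, 3] + th[8] * eta
  l_prev <- numeric(n_mc)
  yk <- NULL
  for (k in seq_len(j)) {
    a_lag <- if (k > 1) a_bar[k - 1] else 0
    v_lag <- if (k > 1) v_bar[k - 1] else 0
    yk <- stats::rnorm(n_mc,
                       mean = th[1] + th[2] * a_lag + th[3] * v_lag +
                         th[4] * l_prev + xb_y,
                       sd = sd_y)
    pl <- expit(mu[1] + mu[2] * v_lag + mu[3] * yk + mu[4] * l_prev +
                  mu[5] * a_lag)
    l_prev <- as.numeric(stats::runif(n_mc) < pl)
  }
  yk
}

#' Marginal causal contrast of the lagged treatment via G-computation
#'
#' Contrasts two regimes identical except for the treatment at interval
#' \code{j - 1}, holding the visit path fixed.  With
#' \code{common_random = TRUE} the two arms share all random draws (common
#' random numbers), which for this linear mechanism removes the Monte Carlo
#' noise from the contrast entirely; with \code{FALSE} the arms are
#' independent and the returned \code{se} is the usual two-sample error.
#'
#' @param config an \code{msm_scenario}.
#' @param j evaluation interval (>= 2 so a lagged treatment exists).
#' @param n_mc Monte Carlo sample size per arm.
#' @param v_bar visit path held fixed across arms; defaults to all 1.
#' @param common_random share random draws across the two arms.
#' @return list with \code{contrast}, \code{se}, \code{n_mc}.
#' @export
gcomp_contrast <- function(config, j = NULL, n_mc = 1e5, v_bar = NULL,
                           common_random = FALSE) {
  stopifnot(inherits(config, "msm_scenario"))
  t <- config$n_intervals
  if (is.null(j)) j <- t
  if (j < 2) stop("j must be >= 2 for a lagged-treatment contrast",
                  call. = FALSE)
  if (is.null(v_bar)) v_bar <- rep(1, t)
  a1 <- a0 <- rep(0, t)
  a1[j - 1] <- 1
  if (common_random) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    seed_state <- get(".Random.seed", envir = globalenv())
    y1 <- gcomp_draw_y(config, a1, v_bar, j, n_mc)
    assign(".Random.seed", seed_state, envir = globalenv())
    y0 <- gcomp_draw_y(config, a0, v_bar, j, n_mc)
    d <- y1 - y0
    list(contrast = mean(d), se = stats::sd(d) / sqrt(n_mc), n_mc = n_mc)
  } else {
    y1 <- gcomp_draw_y(config, a1, v_bar, j, n_mc)
    y0 <- gcomp_draw_y(config, a0, v_bar, j, n_mc)
    list(contrast = mean(y1) - mean(y0),
         se = sqrt(stats::var(y1) / n_mc + stats::var(y0) / n_mc),
         n_mc = n_mc)
  }
}

#' True marginal effect of the lagged treatment
#'
#' For the identity-link linear outcome model without interactions the
#' marginal causal coefficient of \eqn{a_{j-1}} equals \eqn{\theta_1}
#' exactly; [gcomp_contrast()] provides the Monte Carlo confirmation.
#'
#' @param config an \code{msm_scenario}.
#' @return scalar \eqn{\psi_1 = \theta_1}.
#' @export
true_psi <- function(config) {
  stopifnot(inherits(config, "msm_scenario"))
  config$theta[2]
}
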