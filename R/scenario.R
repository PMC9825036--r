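#' Scenario configuration for the longitudinal data-generating mechanism
#'
#' Bundles every coefficient of the conditional data-generating mechanism
#' (outcome, confounder, visit and treatment models), the outcome variance,
#' the panel dimensions and the two structural flags (irregular visits,
#' subject-level unmeasured confounder) into a validated configuration
#' object.
#'
#' The conditional models are, for subject i and interval j (all lagged
#' values are 0 before the first interval):
#' \itemize{
#'   \item visit:      \eqn{P(V_j = 1) = expit(\omega_0 + \omega_1 L_{j-1} +
#'         \omega_2 X_1 + \omega_3 X_2 + \omega_4 X_3)}
#'   \item outcome:    \eqn{Y_j \sim N(\theta_0 + \theta_1 A_{j-1} +
#'         \theta_2 V_{j-1} + \theta_3 L_{j-1} + \theta_4 X_1 + \theta_5 X_2 +
#'         \theta_6 X_3 + \theta_7 \eta, \sigma^2_Y)}, drawn only at visits
#'   \item confounder: \eqn{P(L_j = 1) = expit(\mu_0 + \mu_1 V_{j-1} +
#'         \mu_2 Y_j + \mu_3 L_{j-1} + \mu_4 A_{j-1})}
#'   \item treatment:  \eqn{P(A_j = 1) = expit(\alpha_0 + \alpha_1 V_{j-1} +
#'         \alpha_2 Y_j + \alpha_3 L_j + \alpha_4 A_{j-1} + \alpha_5 X_1 +
#'         \alpha_6 X_2 + \alpha_7 X_3 + \alpha_8 \eta)}
#' }
#'
#' When \code{unmeasured_confounder} is \code{FALSE}, the latent-confounder
#' loadings \code{theta[8]} (\eqn{\theta_7}) and \code{alpha[9]}
#' (\eqn{\alpha_8}) are forced to 0.  When \code{irregular_visits} is
#' \code{FALSE}, the visit intercept \eqn{\omega_0} is set to 16 so that the
#' visit probability is 1 up to numerical precision (regular repeat
#' measures); otherwise \eqn{\omega_0 = 2} under the default parameters.
#'
#' @param theta numeric length 8: outcome coefficients
#'   \eqn{\theta_0..\theta_7} (\eqn{\theta_7} multiplies the latent
#'   confounder \eqn{\eta}).
#' @param sigma2_y positive scalar, outcome variance \eqn{\sigma^2_Y}.
#' @param mu numeric length 5: confounder coefficients \eqn{\mu_0..\mu_4}.
#' @param omega numeric length 5: visit coefficients \eqn{\omega_0..\omega_4}.
#' @param alpha numeric length 9: treatment coefficients
#'   \eqn{\alpha_0..\alpha_8} (\eqn{\alpha_8} multiplies \eqn{\eta}).
#' @param n_subjects number of subjects per simulated panel.
#' @param n_intervals number of discrete time intervals.
#' @param irregular_visits logical; if \code{FALSE} the visit intercept is
#'   forced to the regular-visit value 16.
#' @param unmeasured_confounder logical; if \code{FALSE} the latent loadings
#'   are forced to 0.
#' @param n_replicates number of Monte Carlo replicates in a scenario run.
#' @param seed integer base seed.
#' @return an object of class \code{msm_scenario} (a named list).
#' @seealso [scenario_config()] for the four standard study scenarios.
#' @export
new_scenario <- function(theta = c(9, -0.3, -0.1, 0.5, 0.5, 0.5, 0.5, 0.1),
                         sigma2_y = 3,
                         mu = c(0, 0.1, 0, 0, 0.1),
                         omega = c(2, 0.1, 0.1, 0.1, 0.1),
                         alpha = c(0, 0.1, 0.1, 0.1, 0, 0.3, 0.3, 0.6, 0.1),
                         n_subjects = 100L,
                         n_intervals = 10L,
                         irregular_visits = TRUE,
                         unmeasured_confounder = TRUE,
                         n_replicates = 1000L,
                         seed = 1L) {
  stopifnot(length(theta) == 8, length(mu) == 5, length(omega) == 5,
            length(alpha) == 9, is.numeric(sigma2_y), length(sigma2_y) == 1)
  if (n_subjects < 1 || n_intervals < 1)
    stop("n_subjects and n_intervals must both be >= 1", call. = FALSE)
  if (sigma2_y <= 0) stop("sigma2_y must be > 0", call. = FALSE)
  if (!isTRUE(unmeasured_confounder)) {
    theta[8] <- 0
    alpha[9] <- 0
  }
  if (!isTRUE(irregular_visits)) omega[1] <- 16
  cfg <- list(theta = as.numeric(theta),
              sigma2_y = as.numeric(sigma2_y),
              mu = as.numeric(mu),
              omega = as.numeric(omega),
              alpha = as.numeric(alpha),
              n_subjects = as.integer(n_subjects),
              n_intervals = as.integer(n_intervals),
              irregular_visits = isTRUE(irregular_visits),
              unmeasured_confounder = isTRUE(unmeasured_confounder),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  class(cfg) <- "msm_scenario"
  cfg
}

#' Standard simulation-study scenarios
#'
#' The four-scenario factorial of irregular visits x unmeasured confounder
#' used throughout the simulation study, at the study's default coefficient
#' values (n = 100 subjects, 10 intervals, 1000 replicates):
#' \describe{
#'   \item{1}{regular visits, no unmeasured confounder}
#'   \item{2}{regular visits, unmeasured confounder}
#'   \item{3}{irregular visits, no unmeasured confounder}
#'   \item{4}{irregular visits, unmeasured confounder}
#' }
#'
#' @param scenario integer in 1..4.
#' @param ... overrides forwarded to [new_scenario()] (e.g. \code{n_subjects},
#'   \code{seed}).
#' @return an \code{msm_scenario}.
#' @export
scenario_config <- function(scenario, ...) {
  scenario <- as.integer(scenario)
  if (length(scenario) != 1 || is.na(scenario) || scenario < 1 || scenario > 4)
    stop("scenario must be a single integer in 1..4", call. = FALSE)
  new_scenario(irregular_visits = scenario %in% c(3L, 4L),
               unmeasured_confounder = scenario %in% c(2L, 4L),
               ...)
}

#' @export
print.msm_scenario <- function(x, ...) {
  cat("<msm_scenario>\n")
  cat(sprintf("  subjects: %d, intervals: %d, replicates: %d, seed: %d\n",
              x$n_subjects, x$n_intervals, x$n_replicates, x$seed))
  cat(sprintf("  irregular visits: %s, unmeasured confounder: %s\n",
              x$irregular_visits, x$unmeasured_confounder))
  cat("  theta:", paste(format(x$theta), collapse = " "),
      " sigma2_y:", format(x$sigma2_y), "\n")
  cat("  mu:   ", paste(format(x$mu), collapse = " "), "\n")
  cat("  omega:", paste(format(x$omega), collapse = " "), "\n")
  cat("  alpha:", paste(format(x$alpha), collapse = " "), "\n")
  invisible(x)
}

#' Read / write scenario configurations as YAML
#'
#' The YAML keys mirror the fields of [new_scenario()].  Flags and
#' dimensions are applied through the constructor, so a file with
#' \code{unmeasured_confounder: false} gets its latent loadings zeroed on
#' read just as the constructor would.
#'
#' @param path file path.
#' @return \code{read_scenario_yaml} returns an \code{msm_scenario};
#'   \code{write_scenario_yaml} returns \code{path} invisibly.
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(new_scenario)))
  do.call(new_scenario, raw[keep])
}

#' @rdname read_scenario_yaml
#' @param config an \code{msm_scenario}.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "msm_scenario"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
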