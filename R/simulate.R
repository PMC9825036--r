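#' Numerically stable inverse-logit
#'
#' \code{expit(x) = exp(x) / (1 + exp(x))}, evaluated so that large
#' positive or negative arguments do not overflow.
#'
#' @param x numeric vector.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' Baseline covariates
#'
#' Draws, for each subject, a trivariate standard-normal vector
#' \eqn{U = (U_1, U_2, U_3)} and returns the deterministic transform
#' \deqn{X = ( \exp(U_1/2),\; U_1 / (1 + \exp(U_2)),\; U_1 U_3 / 25 ).}
#'
#' @param n number of subjects (>= 1).
#' @return numeric matrix n x 3 with columns \code{x1, x2, x3}.
#' @export
draw_baseline_covariates <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  baseline_transform(cbind(stats::rnorm(n), stats::rnorm(n),
                           stats::rnorm(n)))
}

#' @rdname draw_baseline_covariates
#' @param u numeric matrix n x 3 of latent standard-normal draws.
#' @export
baseline_transform <- function(u) {
  u <- matrix(u, ncol = 3)
  cbind(x1 = exp(u[, 1] / 2),
        x2 = u[, 1] / (1 + exp(u[, 2])),
        x3 = u[, 1] * u[, 3] / 25)
}

#' Simulate a longitudinal panel with visit-driven carry-forward
#'
#' Generates one panel from the conditional data-generating mechanism of
#' [new_scenario()].  Within each interval the draws follow the topological
#' order visit -> outcome -> confounder -> treatment.  At a non-visit
#' interval (\eqn{V_{ij} = 0}) nothing is drawn: treatment and confounder
#' are carried forward from the previous interval and the outcome is
#' missing.  The subject-level latent confounder \eqn{\eta_i \sim N(0,1)}
#' is drawn first, then the baseline covariates, then the interval loop.
#'
#' @param config an \code{msm_scenario}.
#' @return an object of class \code{msm_panel}: a list with binary matrices
#'   \code{V}, \code{A}, \code{L} (n x t), outcome matrices \code{Y_latent}
#'   and \code{Y_obs} (identical here; \code{NA} where \eqn{V = 0}),
#'   baseline matrix \code{X} (n x 3), latent vector \code{eta} and the
#'   generating \code{config}.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "msm_scenario"))
  n <- config$n_subjects; t <- config$n_intervals
  th <- config$theta; mu <- config$mu; om <- config$omega; al <- config$alpha
  sd_y <- sqrt(config$sigma2_y)

  eta <- stats::rnorm(n)
  X <- draw_baseline_covariates(n)
  xb_v <- om[3] * X[, 1] + om[4] * X[, 2] + om[5] * X[, 3]
  xb_y <- th[5] * X[, 1] + th[6] * X[, 2] + th[7] * X[, 3] + th[8] * eta
  xb_a <- al[6] * X[, 1] + al[7] * X[, 2] + al[8] * X[, 3] + al[9] * eta

  V <- A <- L <- matrix(0L, n, t)
  Y <- matrix(NA_real_, n, t)
  v_prev <- a_prev <- l_prev <- integer(n)  # virtual interval-0 values

  for (j in seq_len(t)) {
    pv <- expit(om[1] + om[2] * l_prev + xb_v)
    vj <- as.integer(stats::runif(n) < pv)
    at_visit <- vj == 1L

    aj <- a_prev; lj <- l_prev
    if (any(at_visit)) {
      idx <- which(at_visit)
      yj <- stats::rnorm(length(idx),
                         mean = th[1] + th[2] * a_prev[idx] +
                           th[3] * v_prev[idx] + th[4] * l_prev[idx] +
                           xb_y[idx],
                         sd = sd_y)
      pl <- expit(mu[1] + mu[2] * v_prev[idx] + mu[3] * yj +
                    mu[4] * l_prev[idx] + mu[5] * a_prev[idx])
      lj[idx] <- as.integer(stats::runif(length(idx)) < pl)
      pa <- expit(al[1] + al[2] * v_prev[idx] + al[3] * yj +
                    al[4] * lj[idx] + al[5] * a_prev[idx] + xb_a[idx])
      aj[idx] <- as.integer(stats::runif(length(idx)) < pa)
      Y[idx, j] <- yj
    }
    V[, j] <- vj; A[, j] <- aj; L[, j] <- lj
    v_prev <- vj; a_prev <- aj; l_prev <- lj
  }

  structure(list(V = V, A = A, L = L, Y_latent = Y, Y_obs = Y,
                 X = X, eta = eta, config = config),
            class = "msm_panel")
}

#' @export
print.msm_panel <- function(x, ...) {
  cat(sprintf("<msm_panel> %d subjects x %d intervals; visit rate %.3f\n",
              nrow(x$V), ncol(x$V), mean(x$V)))
  invisible(x)
}

#' Long-format conversion and CSV round trip
#'
#' One row per (subject, interval) with columns \code{id, interval, visit,
#' treatment, confounder, outcome, x1, x2, x3}; the outcome field is empty
#' in the CSV where the visit indicator is 0.
#'
#' @param panel an \code{msm_panel}.
#' @return \code{panel_to_long} returns a \code{data.frame}.
#' @export
panel_to_long <- function(panel) {
  stopifnot(inherits(panel, "msm_panel"))
  n <- nrow(panel$V); t <- ncol(panel$V)
  data.frame(id = rep(seq_len(n), times = t),
             interval = rep(seq_len(t), each = n),
             visit = as.integer(panel$V),
             treatment = as.integer(panel$A),
             confounder = as.integer(panel$L),
             outcome = as.numeric(panel$Y_obs),
             x1 = rep(panel$X[, 1], times = t),
             x2 = rep(panel$X[, 2], times = t),
             x3 = rep(panel$X[, 3], times = t))
}

#' @rdname panel_to_long
#' @param path CSV file path.
#' @export
write_panel_csv <- function(panel, path) {
  long <- panel_to_long(panel)
  long <- long[order(long$id, long$interval), ]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @return \code{read_panel_csv} returns an \code{msm_panel} (with empty
#'   \code{eta} and \code{NULL} config: the latent state is not part of the
#'   observed-data exchange format).
#' @export
read_panel_csv <- function(path) {
  long <- utils::read.csv(path, na.strings = "")
  need <- c("id", "interval", "visit", "treatment", "confounder",
            "outcome", "x1", "x2", "x3")
  if (!all(need %in% names(long)))
    stop("panel CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- sort(unique(long$id)); n <- length(ids); t <- max(long$interval)
  long$.i <- match(long$id, ids)
  mk <- function(col, mode = "integer") {
    m <- matrix(if (mode == "integer") NA_integer_ else NA_real_, n, t)
    m[cbind(long$.i, long$interval)] <-
      if (mode == "integer") as.integer(long[[col]]) else long[[col]]
    m
  }
  X <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  first <- long[!duplicated(long$.i), ]
  X[first$.i, ] <- as.matrix(first[, c("x1", "x2", "x3")])
  Y <- mk("outcome", "double")
  structure(list(V = mk("visit"), A = mk("treatment"), L = mk("confounder"),
                 Y_latent = Y, Y_obs = Y, X = X,
                 eta = rep(NA_real_, n), config = NULL),
            class = "msm_panel")
}
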