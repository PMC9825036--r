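#' History terms available as pooled-logistic regressors
#'
#' Builds the person-interval design matrix for a set of named history
#' terms, stacked interval-major (all subjects at interval 1, then all at
#' interval 2, ...), the cell order used throughout the package.
#' Recognised terms:
#' \describe{
#'   \item{v_lag, a_lag, l_lag}{previous-interval visit / treatment /
#'     confounder (0 before the first interval)}
#'   \item{l_cur}{current-interval confounder (carried forward at
#'     non-visits, as generated)}
#'   \item{last_y_incl}{most recently observed outcome up to and including
#'     the current interval (0 before the first observed outcome)}
#'   \item{last_y_prev}{most recently observed outcome strictly before the
#'     current interval}
#'   \item{x1, x2, x3}{baseline covariates}
#'   \item{a2_lag, cc_a_lag, cc_a2_lag}{for two-exposure panels: the lagged
#'     second exposure and the lagged cumulative exposure counts capped at
#'     two, per exposure}
#' }
#' The outcome itself is missing at non-visits, so the carried-forward
#' \code{last_y_*} terms are the usable stand-ins for the outcome history.
#'
#' @param panel an \code{msm_panel}.
#' @param terms character vector of term names (intercept is added by the
#'   fitting routine, not here).
#' @return numeric matrix with \code{n_subjects * n_intervals} rows.
#' @export
panel_design <- function(panel, terms) {
  stopifnot(inherits(panel, "msm_panel"))
  n <- nrow(panel$V); t <- ncol(panel$V)
  lag0 <- function(m) cbind(0L, m[, -t, drop = FALSE])
  lasty <- matrix(0, n, t + 1)  # column j+1 = last observed Y through j
  for (j in seq_len(t)) {
    obs <- !is.na(panel$Y_obs[, j])
    lasty[, j + 1] <- ifelse(obs, panel$Y_obs[, j], lasty[, j])
  }
  get_term <- function(tm) {
    switch(tm,
           v_lag = as.numeric(lag0(panel$V)),
           a_lag = as.numeric(lag0(panel$A)),
           l_lag = as.numeric(lag0(panel$L)),
           l_cur = as.numeric(panel$L),
           last_y_incl = as.numeric(lasty[, -1, drop = FALSE]),
           last_y_prev = as.numeric(lasty[, -(t + 1), drop = FALSE]),
           a2_lag = as.numeric(lag0(panel$A2)),
           cc_a_lag = as.numeric(lag0(pmin(row_cumsum(panel$A), 2))),
           cc_a2_lag = as.numeric(lag0(pmin(row_cumsum(panel$A2), 2))),
           x1 = rep(panel$X[, 1], times = t),
           x2 = rep(panel$X[, 2], times = t),
           x3 = rep(panel$X[, 3], times = t),
           stop("unknown design term: ", tm, call. = FALSE))
  }
  mat <- vapply(terms, get_term, numeric(n * t))
  dim(mat) <- c(n * t, length(terms))
  colnames(mat) <- terms
  mat
}

#' Default numerator/denominator regressor sets
#'
#' The denominator (full-history) models condition on the observed history
#' through the previous interval — lagged visit, the last outcome observed
#' before the interval, lagged confounder, lagged treatment and baseline
#' covariates — following the weight definition
#' \eqn{\Pr(A_j | \bar H_{j-1})}.  The numerator (stabilizing) models drop
#' the time-dependent covariates, keeping only past treatment/visit and
#' baseline covariates.  An alternative "current-information" denominator
#' (\code{l_cur}, \code{last_y_incl}) that mirrors the generating model's
#' own regressors can be supplied explicitly; it makes the stabilized
#' treatment weights fully consistent on their own, leaving calibration
#' nothing to correct.
#'
#' @return nested list \code{$treatment$num/den}, \code{$visit$num/den}.
#' @export
default_weight_specs <- function() {
  list(treatment = list(
         num = c("v_lag", "a_lag", "x1", "x2", "x3"),
         den = c("v_lag", "last_y_prev", "l_lag", "a_lag", "x1", "x2", "x3")),
       visit = list(
         num = c("v_lag", "x1", "x2", "x3"),
         den = c("v_lag", "last_y_prev", "l_lag", "x1", "x2", "x3")))
}

#' Pooled logistic regression over person-intervals
#'
#' Maximum-likelihood logistic fit of the treatment or visit indicator on
#' history terms, pooled over all person-intervals, by iteratively
#' reweighted least squares (tolerance 1e-8 on the coefficient change,
#' at most 100 iterations).  Perfect separation (or any failure to
#' converge) is flagged, not silently accepted; a response without
#' variation is an error.
#'
#' @param panel an \code{msm_panel}.
#' @param event \code{"treatment"} or \code{"visit"}.
#' @param regressor_spec character vector of [panel_design()] terms; the
#'   intercept is always included.
#' @param cells optional logical n x t matrix marking the person-intervals
#'   where the event is genuinely stochastic and hence modelled.  The
#'   treatment can only change at a visit (elsewhere it is the
#'   deterministic carry-forward, probability one), so treatment models
#'   default to visit cells only; visit models use every cell.  Fitted
#'   probabilities are still evaluated at every cell.
#' @return an object of class \code{msm_logit}: coefficients, an n x t
#'   matrix \code{fitted} of event probabilities, an n x t matrix
#'   \code{prob_observed} of probabilities of the observed value, the
#'   modelled-\code{cells} matrix, \code{converged}, and the spec.
#' @export
fit_pooled_logistic <- function(panel, event = c("treatment", "visit"),
                                regressor_spec, cells = NULL) {
  event <- match.arg(event)
  if (is.null(cells)) {
    cells <- if (event == "treatment") panel$V == 1L
    else matrix(TRUE, nrow(panel$V), ncol(panel$V))
  }
  y_full <- as.numeric(if (event == "treatment") panel$A else panel$V)
  use <- as.vector(cells)
  y <- y_full[use]
  if (length(unique(y)) < 2)
    stop("degenerate fit: the ", event, " indicator is constant",
         call. = FALSE)
  Xd_full <- cbind("(Intercept)" = 1, panel_design(panel, regressor_spec))
  Xd <- Xd_full[use, , drop = FALSE]
  beta <- numeric(ncol(Xd))
  converged <- FALSE
  for (it in seq_len(100L)) {
    eta <- drop(Xd %*% beta)
    p <- expit(eta)
    w <- pmax(p * (1 - p), 1e-12)
    score <- crossprod(Xd, y - p)
    step <- tryCatch(solve(crossprod(Xd, Xd * w), score),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 30) converged <- FALSE  # separation signature
  p <- expit(drop(Xd %*% beta))
  n <- nrow(panel$V); t <- ncol(panel$V)
  p_full <- expit(drop(Xd_full %*% beta))
  fitted <- matrix(p_full, n, t)
  prob_obs <- matrix(ifelse(y_full == 1, p_full, 1 - p_full), n, t)
  structure(list(coefficients = stats::setNames(drop(beta), colnames(Xd)),
                 fitted = fitted, prob_observed = prob_obs,
                 cells = cells,
                 regressor_spec = regressor_spec, event = event,
                 converged = converged,
                 score_max = max(abs(crossprod(Xd, y - p)))),
            class = "msm_logit")
}

#' @export
print.msm_logit <- function(x, ...) {
  cat(sprintf("<msm_logit> pooled %s model%s\n", x$event,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

# internal constructor for a weight set
new_weight_set <- function(sw, kind, numerator_fit = NULL,
                           denominator_fit = NULL, panel = NULL) {
  structure(list(sw = sw, kind = kind, numerator_fit = numerator_fit,
                 denominator_fit = denominator_fit, panel = panel),
            class = "msm_weights")
}

#' @export
print.msm_weights <- function(x, ...) {
  cat(sprintf("<msm_weights> kind: %s; %d x %d; range [%.4g, %.4g]\n",
              x$kind, nrow(x$sw), ncol(x$sw), min(x$sw), max(x$sw)))
  invisible(x)
}

#' Unit weights
#'
#' All-ones weight set matching a panel, for the naive (unweighted)
#' estimator and as the identity element of [product_weights()].
#'
#' @param panel an \code{msm_panel}.
#' @export
unit_weights <- function(panel) {
  new_weight_set(matrix(1, nrow(panel$V), ncol(panel$V)), "unit",
                 panel = panel)
}

#' Stabilized cumulative-product inverse probability weights
#'
#' Fits numerator and denominator pooled logistic models and forms, per
#' subject and interval t, the cumulative product over intervals j <= t of
#' the ratio of numerator to denominator probabilities of the observed
#' event value.
#'
#' @param panel an \code{msm_panel}.
#' @param event \code{"treatment"} or \code{"visit"}.
#' @param numerator_spec,denominator_spec regressor term vectors; default
#'   to [default_weight_specs()] for the event.
#' @return an \code{msm_weights} with \code{kind} equal to \code{event}.
#' @export
stabilized_weights <- function(panel, event = c("treatment", "visit"),
                               numerator_spec = NULL,
                               denominator_spec = NULL) {
  event <- match.arg(event)
  specs <- default_weight_specs()[[event]]
  if (is.null(numerator_spec)) numerator_spec <- specs$num
  if (is.null(denominator_spec)) denominator_spec <- specs$den
  num <- fit_pooled_logistic(panel, event, numerator_spec)
  den <- fit_pooled_logistic(panel, event, denominator_spec)
  bad <- which(den$prob_observed <= .Machine$double.eps & den$cells,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "positivity violation: denominator probability 0 at subject %d, interval %d",
      bad[1, 1], bad[1, 2]), call. = FALSE)
  ratio <- num$prob_observed / den$prob_observed
  # where the event is deterministic (treatment between visits) both
  # conditional probabilities are 1 and the interval contributes ratio 1
  ratio[!den$cells] <- 1
  sw <- t(apply(ratio, 1, cumprod))
  if (ncol(panel$V) == 1) sw <- matrix(sw, ncol = 1)
  new_weight_set(sw, event, num, den, panel)
}

#' Product of weight families across exposures
#'
#' Cellwise product of aligned weight sets, e.g. joint treatment-and-visit
#' weights or multi-exposure products.  Order-invariant.
#'
#' @param parts list of \code{msm_weights} with identical dimensions.
#' @return an \code{msm_weights} of kind \code{"product"}.
#' @export
product_weights <- function(parts) {
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, TRUE,
                                           "msm_weights")))
  dims <- vapply(parts, function(p) dim(p$sw), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("weight sets are not aligned on (subject, interval)", call. = FALSE)
  sw <- Reduce(`*`, lapply(parts, `[[`, "sw"))
  new_weight_set(sw, "product", panel = parts[[1]]$panel)
}

#' Export weights as long-format CSV
#'
#' Columns \code{id, interval, weight, kind}, one row per person-interval.
#'
#' @param w an \code{msm_weights}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_weights_csv <- function(w, path) {
  stopifnot(inherits(w, "msm_weights"))
  n <- nrow(w$sw); t <- ncol(w$sw)
  long <- data.frame(id = rep(seq_len(n), times = t),
                     interval = rep(seq_len(t), each = n),
                     weight = as.numeric(w$sw),
                     kind = w$kind)
  utils::write.csv(long[order(long$id, long$interval), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' Winsorize weights at pooled empirical quantiles
#'
#' Truncation at (for example) the 1\% and 99\% quantiles of the pooled
#' weight distribution, the usual guard against extreme inverse
#' probability weights in applications.  Uses the linear-interpolation
#' sample quantile (R type 7).
#'
#' @param w an \code{msm_weights}.
#' @param lower_q,upper_q quantile probabilities, 0 <= lower < upper <= 1.
#' @return an \code{msm_weights} with winsorized weights.
#' @export
truncate_weights <- function(w, lower_q = 0.01, upper_q = 0.99) {
  stopifnot(inherits(w, "msm_weights"),
            lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  bounds <- stats::quantile(w$sw, c(lower_q, upper_q), names = FALSE)
  out <- w
  out$sw <- pmin(pmax(w$sw, bounds[1]), bounds[2])
  out
}
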