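#' Calibration of stabilized weights by exponential tilting
#'
#' A stabilized weight set is calibrated by multiplying each cell weight by
#' \eqn{c = \exp(K \lambda)}, where K has one row per person-interval and
#' one column per moment restriction, and \eqn{\lambda} solves the system
#' of weighted moment conditions
#' \deqn{g(\lambda) = \sum_{cells} w\, e^{K\lambda} K - targets = 0.}
#' Three restriction families are available:
#' \itemize{
#'   \item balance: the calibrated-weighted cumulative residuals of the
#'     event (treatment or visit) against the stabilizing propensity are
#'     orthogonal to a covariate basis (intercept and lagged confounder by
#'     default);
#'   \item unity: the calibrated weights average to one at every interval;
#'   \item subject: the per-subject cumulative residual sums vanish,
#'     absorbing a time-invariant subject-level unmeasured confounder.
#' }
#' Because the tilt is exponential, calibrated weights stay strictly
#' positive, and \eqn{\lambda = 0} reproduces the base weights exactly.
#'
#' @name calibration
NULL

# row-wise cumulative sum of an n x t matrix
row_cumsum <- function(m) {
  if (ncol(m) == 1) return(m)
  t(apply(m, 1, cumsum))
}

#' Covariate-balance constraint columns
#'
#' For each basis term b the cell-(i, j) entry is the inner cumulative sum
#' \eqn{\sum_{k \le j} (event_{ik} - \hat e_{ik})\, b_{ik}}; the restriction
#' is that the calibrated-weighted total of the column is zero.
#'
#' @param panel an \code{msm_panel}.
#' @param residuals n x t matrix of (event - fitted propensity) residuals.
#' @param covariate_basis named list of n x t basis matrices, or the name
#'   of a built-in basis: \code{"treatment"} gives intercept, current and
#'   lagged confounder (the treatment at an interval responds to the
#'   confounder drawn in that interval, so balancing against the current
#'   value targets the under-adjustment that lagged-history propensities
#'   leave behind); \code{"visit"} gives intercept and lagged confounder
#'   only (the current confounder is realized after the visit indicator
#'   and must not be balanced against it).
#' @return matrix with \code{n * t} rows, one column per basis term.
#' @export
build_balance_constraints <- function(panel, residuals,
                                      covariate_basis = "treatment") {
  n <- nrow(residuals); t <- ncol(residuals)
  if (is.character(covariate_basis)) {
    covariate_basis <- if (match.arg(covariate_basis,
                                     c("treatment", "visit")) == "treatment")
      list(intercept = matrix(1, n, t),
           l_cur = matrix(panel_design(panel, "l_cur"), n, t),
           l_lag = matrix(panel_design(panel, "l_lag"), n, t))
    else
      list(intercept = matrix(1, n, t),
           l_lag = matrix(panel_design(panel, "l_lag"), n, t))
  }
  cols <- vapply(covariate_basis,
                 function(b) as.numeric(row_cumsum(residuals * b)),
                 numeric(n * t))
  dim(cols) <- c(n * t, length(covariate_basis))
  colnames(cols) <- names(covariate_basis)
  cols
}

#' Unity-mean constraint columns
#'
#' One indicator column per interval; the target is n (the sum of the
#' calibrated weights at each interval equals n, i.e. their mean is one).
#'
#' @param n_subjects,n_intervals panel dimensions.
#' @return list with \code{K} (indicator columns) and \code{targets}.
#' @export
build_unity_constraints <- function(n_subjects, n_intervals) {
  K <- matrix(0, n_subjects * n_intervals, n_intervals)
  for (j in seq_len(n_intervals))
    K[(j - 1) * n_subjects + seq_len(n_subjects), j] <- 1
  colnames(K) <- paste0("unity_t", seq_len(n_intervals))
  list(K = K, targets = rep(as.numeric(n_subjects), n_intervals))
}

#' Per-subject latent-confounder constraint columns
#'
#' One column per subject holding that subject's cumulative residual sums
#' on its own cells and zero elsewhere; target zero.  Summed over subjects
#' these columns reproduce the intercept balance column, which is
#' therefore dropped when this family is active.
#'
#' @param panel an \code{msm_panel}.
#' @param residuals n x t residual matrix.
#' @return matrix with \code{n * t} rows and one column per subject.
#' @export
build_subject_constraints <- function(panel, residuals) {
  n <- nrow(residuals); t <- ncol(residuals)
  cum <- row_cumsum(residuals)
  K <- matrix(0, n * t, n)
  cell_subject <- rep(seq_len(n), times = t)
  K[cbind(seq_len(n * t), cell_subject)] <- as.numeric(cum)
  colnames(K) <- paste0("subject_", seq_len(n))
  K
}

#' Per-interval latent-confounder constraint columns
#'
#' One column per interval j holding the cumulative residual sums
#' \eqn{\sum_{k \le j} (event_{ik} - \hat e_{ik})} on the interval-j cells
#' and zero elsewhere; target zero.  In the calibrated pseudo-population
#' the cumulative event residuals are balanced to zero within each time
#' interval, which absorbs the drift a time-invariant subject-level
#' confounder induces in the residual process while keeping the tilt
#' population-level and gentle.  This is the restriction family the
#' scenario studies use; [build_subject_constraints()] is the hard
#' per-subject variant, which generically admits only boundary solutions
#' (weights driven to zero for subjects whose cumulative residuals never
#' change sign — for instance subjects treated at every interval).
#'
#' @param panel an \code{msm_panel}.
#' @param residuals n x t residual matrix.
#' @return matrix with \code{n * t} rows and one column per interval.
#' @export
build_latent_constraints <- function(panel, residuals) {
  n <- nrow(residuals); t <- ncol(residuals)
  cum <- row_cumsum(residuals)
  K <- matrix(0, n * t, t)
  for (j in seq_len(t))
    K[(j - 1) * n + seq_len(n), j] <- cum[, j]
  colnames(K) <- paste0("latent_t", seq_len(t))
  K
}

#' Assemble a calibration constraint system
#'
#' @param base an \code{msm_weights} (the stabilized weights to calibrate).
#' @param K constraint matrix, one row per cell, one column per constraint.
#' @param targets numeric vector, one per constraint.
#' @return object of class \code{msm_constraints}.
#' @export
new_constraint_system <- function(base, K, targets) {
  stopifnot(inherits(base, "msm_weights"), nrow(K) == length(base$sw),
            ncol(K) == length(targets))
  structure(list(K = K, targets = as.numeric(targets),
                 base = as.numeric(base$sw), base_weights = base),
            class = "msm_constraints")
}

# moment residual and its convex potential; lp clipping is applied only
# when clip = TRUE (line search), never to report a converged solution
cal_resid <- function(lambda, K, base, targets, clip = FALSE) {
  lp <- drop(K %*% lambda)
  if (clip) lp <- pmin(pmax(lp, -50), 50)
  w <- base * exp(lp)
  drop(crossprod(K, w)) - targets
}

cal_potential <- function(lambda, K, base, targets) {
  lp <- pmin(pmax(drop(K %*% lambda), -50), 50)
  sum(base * exp(lp)) - sum(targets * lambda)
}

#' Solve the calibration moment conditions in lambda
#'
#' The moment function is the gradient of the convex potential
#' \eqn{\Phi(\lambda) = \sum w e^{K\lambda} - t'\lambda}, so the root is
#' found by a Barzilai-Borwein spectral gradient iteration with a
#' non-monotone line search, followed (if needed) by damped Newton steps
#' using the analytic Hessian \eqn{K' diag(w e^{K\lambda}) K}.
#' Non-convergence is reported, never silently accepted; a solution
#' sitting on the overflow clip is treated as non-converged.
#'
#' @param system an \code{msm_constraints}.
#' @param tol infinity-norm tolerance on the moment residual.
#' @param max_iter maximum Barzilai-Borwein iterations.
#' @return list of class \code{msm_calibration}: \code{lambda},
#'   \code{calibrated} weights matrix, \code{converged},
#'   \code{residual_norm}, \code{iterations}.
#' @export
solve_lambda <- function(system, tol = 1e-8, max_iter = 5000L) {
  stopifnot(inherits(system, "msm_constraints"))
  K <- system$K; base <- system$base; targets <- system$targets
  r <- ncol(K)
  lambda <- numeric(r)
  iterations <- 0L

  if (r == 0 || all(K == 0)) {
    return(finish_calibration(system, lambda, 0L, tol))
  }

  g <- cal_resid(lambda, K, base, targets)
  f <- cal_potential(lambda, K, base, targets)
  fhist <- rep(f, 10)
  step <- 1 / max(1, sqrt(sum(g^2)))
  bb_iter <- min(max_iter, 300L)  # Newton fallback handles the tail
  for (it in seq_len(bb_iter)) {
    iterations <- it
    if (max(abs(g)) <= tol) break
    d <- -step * g
    # non-monotone (Grippo) backtracking on the potential
    sigma <- 1
    fmax <- max(fhist)
    repeat {
      cand <- lambda + sigma * d
      fc <- cal_potential(cand, K, base, targets)
      if (fc <= fmax - 1e-4 * sigma^2 * sum(d^2) || sigma < 1e-10) break
      sigma <- sigma / 2
    }
    gc_new <- cal_resid(cand, K, base, targets, clip = TRUE)
    s <- cand - lambda
    yv <- gc_new - g
    sy <- sum(s * yv)
    step <- if (sy > 1e-300) sum(s * s) / sy else 1 / max(1, sqrt(sum(gc_new^2)))
    step <- min(max(step, 1e-10), 1e10)
    lambda <- cand
    g <- gc_new
    f <- fc
    fhist <- c(fhist[-1], f)
  }

  if (max(abs(cal_resid(lambda, K, base, targets))) > tol) {
    # damped Newton fallback on the convex potential
    for (it in seq_len(min(max_iter, 200L))) {
      iterations <- iterations + 1L
      lp <- pmin(pmax(drop(K %*% lambda), -50), 50)
      w <- base * exp(lp)
      g <- drop(crossprod(K, w)) - targets
      if (max(abs(g)) <= tol) break
      H <- crossprod(K, K * w)
      diag(H) <- diag(H) + 1e-10
      d <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(d)) break
      sigma <- 1
      f0 <- cal_potential(lambda, K, base, targets)
      repeat {
        cand <- lambda + sigma * d
        if (cal_potential(cand, K, base, targets) < f0 || sigma < 1e-12) break
        sigma <- sigma / 2
      }
      if (sigma < 1e-12) break
      lambda <- cand
    }
  }

  finish_calibration(system, lambda, iterations, tol)
}

finish_calibration <- function(system, lambda, iterations, tol) {
  K <- system$K; base <- system$base; targets <- system$targets
  g <- cal_resid(lambda, K, base, targets)
  resid_norm <- if (length(g)) max(abs(g)) else 0
  lp <- if (length(lambda)) drop(K %*% lambda) else numeric(length(base))
  # weights may legitimately tilt toward zero under per-subject latent
  # restrictions (boundary solutions); only exploding weights or a
  # non-vanishing residual count as failure
  at_clip <- length(lp) > 0 && max(lp) >= 50
  converged <- resid_norm <= tol && !at_clip && all(is.finite(lp))
  sw0 <- system$base_weights$sw
  calibrated <- system$base_weights
  calibrated$sw <- sw0 * matrix(exp(lp), nrow(sw0), ncol(sw0))
  calibrated$kind <- paste0("calibrated_", system$base_weights$kind)
  structure(list(lambda = lambda, calibrated = calibrated,
                 converged = converged, residual_norm = resid_norm,
                 iterations = iterations, system = system),
            class = "msm_calibration")
}

#' @export
print.msm_calibration <- function(x, ...) {
  cat(sprintf(
    "<msm_calibration> %d constraints; converged: %s; residual %.3g; %d iterations\n",
    ncol(x$system$K), x$converged, x$residual_norm, x$iterations))
  invisible(x)
}

#' Calibrate a stabilized weight set
#'
#' Assembles the requested restriction families against the stabilizing
#' (numerator) propensity fit, prunes redundant columns (the intercept
#' balance column equals the sum of the subject columns and is dropped
#' when both are active; zero columns are dropped), and solves for lambda.
#'
#' @param base an \code{msm_weights} of kind \code{"treatment"} or
#'   \code{"visit"} carrying its fits and panel.
#' @param options character subset of
#'   \code{c("balance", "unity", "latent", "subject")}: covariate balance,
#'   unity mean per interval, per-interval latent-confounder balance (the
#'   scenario-study default for unmeasured-confounder scenarios), and the
#'   hard per-subject restriction (see [build_latent_constraints()] for
#'   the distinction).
#' @param covariate_basis optional basis list for the balance family (see
#'   [build_balance_constraints()]).
#' @param tol,max_iter solver controls.
#' @return an \code{msm_calibration}.
#' @export
calibrate <- function(base, options = c("balance", "unity"),
                      covariate_basis = NULL, tol = 1e-8,
                      max_iter = 5000L) {
  stopifnot(inherits(base, "msm_weights"))
  options <- match.arg(options, c("balance", "unity", "latent", "subject"),
                       several.ok = TRUE)
  panel <- base$panel
  if (is.null(panel) || is.null(base$numerator_fit))
    stop("base weights must carry their panel and numerator fit",
         call. = FALSE)
  event_mat <- if (base$kind == "treatment") panel$A else panel$V
  # residuals only where the event is modelled; deterministic
  # carry-forward cells carry no balancing information
  residuals <- (event_mat - base$numerator_fit$fitted) *
    base$numerator_fit$cells

  if (is.null(covariate_basis)) covariate_basis <- base$kind
  Kparts <- list(); targets <- numeric(0)
  if ("balance" %in% options) {
    Kb <- build_balance_constraints(panel, residuals, covariate_basis)
    # the intercept balance column is the sum of the per-subject columns
    # and also of the per-interval latent columns: drop it when redundant
    if (any(c("subject", "latent") %in% options) &&
        "intercept" %in% colnames(Kb))
      Kb <- Kb[, setdiff(colnames(Kb), "intercept"), drop = FALSE]
    Kparts <- c(Kparts, list(Kb)); targets <- c(targets, numeric(ncol(Kb)))
  }
  if ("unity" %in% options) {
    u <- build_unity_constraints(nrow(panel$V), ncol(panel$V))
    Kparts <- c(Kparts, list(u$K)); targets <- c(targets, u$targets)
  }
  if ("latent" %in% options) {
    Kl <- build_latent_constraints(panel, residuals)
    Kparts <- c(Kparts, list(Kl)); targets <- c(targets, numeric(ncol(Kl)))
  }
  if ("subject" %in% options) {
    Ks <- build_subject_constraints(panel, residuals)
    Kparts <- c(Kparts, list(Ks)); targets <- c(targets, numeric(ncol(Ks)))
  }
  K <- do.call(cbind, Kparts)
  keep <- apply(K != 0, 2, any)
  system <- new_constraint_system(base, K[, keep, drop = FALSE],
                                  targets[keep])
  solve_lambda(system, tol = tol, max_iter = max_iter)
}

#' Calibration report
#'
#' Summarizes a calibration run: constraint counts by family, residual
#' max-norms before and after solving, iteration count, and summary
#' statistics of lambda; optionally written as JSON.
#'
#' @param result an \code{msm_calibration}.
#' @param path optional JSON output path.
#' @return a list (invisibly if \code{path} is given).
#' @export
calibration_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "msm_calibration"))
  sys <- result$system
  cn <- colnames(sys$K)
  fam <- ifelse(grepl("^unity_", cn), "unity",
                ifelse(grepl("^latent_", cn), "latent",
                       ifelse(grepl("^subject_", cn), "subject", "balance")))
  before <- cal_resid(numeric(length(result$lambda)), sys$K, sys$base,
                      sys$targets)
  rep <- list(
    constraints = as.list(table(fam)),
    converged = result$converged,
    iterations = result$iterations,
    residual_norm_before = if (length(before)) max(abs(before)) else 0,
    residual_norm_after = result$residual_norm,
    lambda = if (length(result$lambda))
      list(min = min(result$lambda), max = max(result$lambda),
           mean = mean(result$lambda))
    else list(min = 0, max = 0, mean = 0),
    weight_correlation = stats::cor(as.numeric(sys$base),
                                    as.numeric(result$calibrated$sw)))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

#' Independent recomputation of calibration residuals
#'
#' Recomputes every active constraint residual from the calibrated weights
#' and the constraint matrix directly, without reusing solver internals.
#'
#' @param result an \code{msm_calibration}.
#' @return named numeric vector of residuals.
#' @export
calibration_residuals <- function(result) {
  stopifnot(inherits(result, "msm_calibration"))
  K <- result$system$K
  w <- as.numeric(result$calibrated$sw)
  drop(crossprod(K, w)) - result$system$targets
}
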