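#' Weighted generalized estimating equations, identity link
#'
#' Fits the marginal structural outcome model by weighted GEE with a
#' Gaussian working model, identity link, and either AR(1) or independence
#' working correlation.  Rows with a missing outcome (non-visit intervals)
#' are dropped before fitting; AR(1) lags run over consecutive retained
#' rows within a cluster.  Prior weights enter the working covariance as
#' \eqn{V_i = \phi\, W_i^{-1/2} R(\alpha) W_i^{-1/2}} (the convention of
#' the standard GEE software this mirrors), so with independence working
#' correlation the estimating equation reduces to weighted least squares.
#' The robust covariance is the usual sandwich with per-cluster score
#' outer products.
#'
#' @param panel an \code{msm_panel}.
#' @param weights an \code{msm_weights} aligned with the panel (cumulative
#'   weight at each cell is applied to that cell's outcome row).
#' @param formula_terms character vector of [panel_design()] terms for the
#'   marginal model mean (intercept always included), e.g.
#'   \code{c("a_lag", "x1", "x2", "x3")}.
#' @param corr \code{"ar1"} or \code{"independence"}.
#' @param min_interval first interval retained in the outcome regression.
#'   Marginal models with lagged regressors are fitted from interval 2
#'   onward: at interval 1 every lag is the virtual pre-study 0, and
#'   pooling those rows into a model without an interval term shifts the
#'   lagged-treatment coefficient (an intercept offset that no weighting
#'   can remove).  Weight models still use all intervals.
#' @param tol,max_iter Fisher scoring controls.
#' @return object of class \code{msm_gee}: \code{beta}, \code{robust_cov},
#'   \code{robust_se}, \code{ar1_alpha}, \code{scale}, \code{n_clusters},
#'   \code{converged}.
#' @export
fit_weighted_gee <- function(panel, weights, formula_terms,
                             corr = c("ar1", "independence"),
                             min_interval = 1L,
                             tol = 1e-8, max_iter = 50L) {
  corr <- match.arg(corr)
  stopifnot(inherits(panel, "msm_panel"), inherits(weights, "msm_weights"))
  if (!all(dim(weights$sw) == dim(panel$V)))
    stop("weights are not aligned with the panel", call. = FALSE)

  n <- nrow(panel$V); t <- ncol(panel$V)
  y_all <- as.numeric(panel$Y_obs)
  keep <- !is.na(y_all) & rep(seq_len(t), each = n) >= min_interval
  Xd <- cbind("(Intercept)" = 1, panel_design(panel, formula_terms))[keep, ,
                                                                    drop = FALSE]
  y <- y_all[keep]
  w <- as.numeric(weights$sw)[keep]
  id <- rep(seq_len(n), times = t)[keep]
  interval <- rep(seq_len(t), each = n)[keep]
  ord <- order(id, interval)
  Xd <- Xd[ord, , drop = FALSE]; y <- y[ord]; w <- w[ord]; id <- id[ord]

  clusters <- split(seq_along(id), id)
  if (length(clusters) < 2)
    stop("need at least 2 clusters", call. = FALSE)
  p <- ncol(Xd)

  # OLS start
  beta <- drop(solve(crossprod(Xd), crossprod(Xd, y)))
  alpha <- 0; phi <- 1
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    r <- y - drop(Xd %*% beta)
    e <- sqrt(w) * r
    phi <- sum(e^2) / (length(y) - p)
    if (corr == "ar1") {
      num <- 0; npairs <- 0
      for (rows in clusters) {
        ni <- length(rows)
        if (ni > 1) {
          ei <- e[rows]
          num <- num + sum(ei[-ni] * ei[-1])
          npairs <- npairs + ni - 1
        }
      }
      alpha <- if (npairs > p) num / ((npairs - p) * phi) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    lhs <- matrix(0, p, p); rhs <- numeric(p)
    for (rows in clusters) {
      ni <- length(rows)
      Xi <- Xd[rows, , drop = FALSE]
      Vinv_half <- gee_vinv(w[rows], alpha, ni, corr)
      lhs <- lhs + crossprod(Xi, Vinv_half %*% Xi)
      rhs <- rhs + crossprod(Xi, Vinv_half %*% y[rows])
    }
    beta_new <- drop(solve(lhs, rhs))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # sandwich: bread = sum X' V^-1 X, meat = sum (X' V^-1 r)(X' V^-1 r)'
  r <- y - drop(Xd %*% beta)
  bread <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (rows in clusters) {
    Xi <- Xd[rows, , drop = FALSE]
    Vinv <- gee_vinv(w[rows], alpha, length(rows), corr) / phi
    bread <- bread + crossprod(Xi, Vinv %*% Xi)
    u <- crossprod(Xi, Vinv %*% r[rows])
    meat <- meat + tcrossprod(u)
  }
  binv <- solve(bread)
  robust_cov <- binv %*% meat %*% binv
  robust_cov <- (robust_cov + t(robust_cov)) / 2
  names(beta) <- colnames(Xd)
  dimnames(robust_cov) <- list(names(beta), names(beta))
  structure(list(beta = beta, robust_cov = robust_cov,
                 robust_se = sqrt(diag(robust_cov)),
                 ar1_alpha = alpha, scale = phi,
                 n_clusters = length(clusters), corr = corr,
                 converged = converged, formula_terms = formula_terms),
            class = "msm_gee")
}

# W^{1/2} R(alpha)^{-1} W^{1/2}  (the phi-free part of V_i^{-1})
gee_vinv <- function(wi, alpha, ni, corr) {
  sw <- sqrt(wi)
  if (corr == "independence" || ni == 1 || alpha == 0)
    return(diag(wi, ni))
  # closed-form tridiagonal inverse of the AR(1) correlation matrix
  Rinv <- matrix(0, ni, ni)
  d <- 1 - alpha^2
  diag(Rinv) <- c(1, rep(1 + alpha^2, ni - 2), 1) / d
  off <- -alpha / d
  Rinv[cbind(seq_len(ni - 1), seq_len(ni - 1) + 1)] <- off
  Rinv[cbind(seq_len(ni - 1) + 1, seq_len(ni - 1))] <- off
  (sw %o% sw) * Rinv
}

#' @export
print.msm_gee <- function(x, ...) {
  cat(sprintf("<msm_gee> %s working correlation; %d clusters%s\n",
              x$corr, x$n_clusters,
              if (x$converged) "" else " (NOT converged)"))
  out <- cbind(estimate = x$beta, robust_se = x$robust_se)
  print(round(out, 4))
  if (x$corr == "ar1")
    cat(sprintf("  alpha: %.4f  scale: %.4f\n", x$ar1_alpha, x$scale))
  invisible(x)
}

#' Wald confidence interval from a GEE fit
#'
#' @param fit an \code{msm_gee}.
#' @param coef coefficient name.
#' @param level confidence level.
#' @return numeric length-2 vector (lower, upper).
#' @export
wald_ci <- function(fit, coef = "a_lag", level = 0.95) {
  stopifnot(inherits(fit, "msm_gee"))
  if (!coef %in% names(fit$beta))
    stop("unknown coefficient: ", coef, call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$beta[[coef]]
  se <- fit$robust_se[[coef]]
  c(lower = est - z * se, upper = est + z * se)
}
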