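# Negative binomial GLM with log link, per-gene dispersion, and the
# likelihood-ratio test used by the differential-expression stage.
#
# Parameterization: counts y ~ NB(mu, alpha) with Var = mu + alpha * mu^2
# (alpha = 1/size). Mean model log(mu) = log(sf) + X beta. The dispersion
# is estimated per gene by maximizing the (optionally Cox-Reid adjusted)
# profile likelihood; the adjustment subtracts 0.5 * log det(X' W X) and
# removes most of the downward bias of plain ML when the design uses a
# non-trivial share of the 16 residual degrees of freedom.

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# IRLS for fixed dispersion; offset = log(size factors)
nb_irls <- function(y, X, offset, alpha, beta0 = NULL, tol = 1e-8, max_iter = 100L,
                    coef_bound = 30) {
  p <- ncol(X)
  if (is.null(beta0)) {
    eta <- log(pmax(y, 1 / 6))
  } else {
    eta <- offset + pmin(pmax(drop(X %*% beta0), -coef_bound), coef_bound)
  }
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    if (!all(is.finite(z)) || !all(is.finite(sw))) {
      return(list(beta = beta, mu = exp(eta), converged = FALSE, iterations = it))
    }
    fit <- .lm.fit(X * sw, z * sw)
    if (fit$rank < p || anyNA(fit$coefficients)) {
      return(list(beta = beta, mu = exp(eta), converged = FALSE, iterations = it))
    }
    beta_new <- numeric(p)
    beta_new[fit$pivot] <- fit$coefficients
    xb <- pmin(pmax(drop(X %*% beta_new), -coef_bound), coef_bound)
    eta <- offset + xb
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, mu = exp(eta), converged = converged, iterations = it)
}

# profile objective in alpha with the mean fit held fixed
nb_alpha_objective <- function(log_alpha, y, mu, X, cr_adjust) {
  alpha <- exp(log_alpha)
  ll <- nb_loglik(y, mu, alpha)
  if (cr_adjust) {
    w <- mu / (1 + alpha * mu)
    # X full rank and w > 0, so X'WX is positive definite
    ch <- chol(crossprod(X * sqrt(w)))
    p <- ncol(X)
    ll <- ll - sum(log(ch[1L + (seq_len(p) - 1L) * (p + 1L)]))
  }
  ll
}

#' Fit a negative binomial GLM to one gene
#'
#' Log-link NB regression of a gene's counts on a design matrix with
#' `log(size_factors)` as offset. When `dispersion` is `NULL` it is
#' estimated by maximizing the Cox-Reid adjusted profile likelihood
#' (coordinate ascent between the IRLS mean fit and a one-dimensional
#' search over `log(alpha)`), initialized at a method-of-moments value and
#' floored at `1e-8`. Fitted linear predictors are bounded at +/- 30 on the
#' log scale to keep separated or degenerate genes finite.
#'
#' @param y Non-negative counts, one per sample.
#' @param design Full-rank numeric design matrix (samples x coefficients).
#' @param size_factors Positive per-sample size factors.
#' @param dispersion Fixed NB dispersion `alpha`; `NULL` to estimate.
#' @param cr_adjust Use the Cox-Reid adjustment when estimating the
#'   dispersion (default `TRUE`).
#' @return List with `coefficients`, `dispersion`, `loglik` (unadjusted NB
#'   log-likelihood at the fit), `mu`, `converged`, `iterations`.
#' @export
fit_nb_glm <- function(y, design, size_factors = rep(1, length(y)),
                       dispersion = NULL, cr_adjust = TRUE) {
  X <- as.matrix(design)
  if (length(y) != nrow(X)) stop("length(y) != nrow(design)", call. = FALSE)
  if (any(y < 0)) stop("negative counts", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  offset <- log(size_factors)
  lo <- log(1e-8); hi <- log(1e3)

  if (!is.null(dispersion)) {
    fit <- nb_irls(y, X, offset, dispersion)
    return(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                dispersion = dispersion,
                loglik = nb_loglik(y, fit$mu, dispersion),
                mu = fit$mu, converged = fit$converged,
                iterations = fit$iterations))
  }

  # method-of-moments start from a quasi-Poisson style fit
  fit <- nb_irls(y, X, offset, alpha = 1e-4)
  mu <- fit$mu
  alpha <- max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-8)
  alpha <- min(alpha, exp(hi))
  beta <- fit$beta
  converged <- fit$converged
  for (outer in seq_len(25L)) {
    fit <- nb_irls(y, X, offset, alpha, beta0 = beta)
    beta <- fit$beta; mu <- fit$mu; converged <- fit$converged
    # after the first pass, refine in a window around the current value
    iv <- if (outer == 1L) c(lo, hi) else {
      c(max(lo, log(alpha) - 4), min(hi, log(alpha) + 4))
    }
    opt <- stats::optimize(nb_alpha_objective, iv, maximum = TRUE,
                           y = y, mu = mu, X = X, cr_adjust = cr_adjust,
                           tol = 1e-4)
    alpha_new <- exp(opt$maximum)
    done <- abs(log(alpha_new) - log(alpha)) < 1e-4
    alpha <- alpha_new
    if (done) break
  }
  fit <- nb_irls(y, X, offset, alpha, beta0 = beta)
  list(coefficients = stats::setNames(fit$beta, colnames(X)),
       dispersion = alpha,
       loglik = nb_loglik(y, fit$mu, alpha),
       mu = fit$mu, converged = fit$converged && converged,
       iterations = fit$iterations)
}

#' Likelihood-ratio test between two nested NB fits
#'
#' The statistic is `2 * (loglik_full - loglik_reduced)`, clamped at zero
#' (small negative values can arise from convergence tolerance), referred to
#' a chi-square distribution with as many degrees of freedom as the designs
#' differ in columns. Both fits must use the same dispersion — estimate it
#' under the full model and pass it to the reduced fit.
#'
#' @param full,reduced Fits from [fit_nb_glm()].
#' @param df Degrees of freedom (column-count difference between designs).
#' @return List with `lrt_stat` and `p_raw`.
#' @export
lrt_test <- function(full, reduced, df = 1L) {
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(lrt_stat = stat, p_raw = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Holm step-down adjustment of p-values
#'
#' Familywise-error-controlling step-down adjustment: with the p-values
#' sorted ascending, `adj_(i) = max_(j<=i) min(1, (m - j + 1) * p_(j))`,
#' returned in the original order. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs allowed; they
#'   stay NA and do not count toward `m`).
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  stats::p.adjust(p, method = "holm", n = sum(!is.na(p)))
}
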