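#' Gaussian log-likelihood at the least-squares fit
#'
#' Profiled Gaussian log-likelihood of a regression fit,
#' `-(n/2) * log(2*pi*sigma2) - rss / (2*sigma2)`.  Plugging in the
#' maximum-likelihood variance `sigma2 = rss/n` gives the closed form
#' `-(n/2) * (log(2*pi*sigma2) + 1)`.
#'
#' @param rss Residual sum of squares (nonnegative).
#' @param n Number of observations (positive integer).
#' @param sigma2 Error variance (strictly positive).
#' @return The log-likelihood value.
#' @export
log_likelihood_gaussian <- function(rss, n, sigma2) {
  stopifnot(rss >= 0, n >= 1)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be strictly positive", call. = FALSE)
  }
  -(n / 2) * log(2 * pi * sigma2) - rss / (2 * sigma2)
}

#' Maximum-likelihood variance estimator
#'
#' The ML estimator of the error variance divides the residual sum of
#' squares by `n` (not by residual degrees of freedom).
#'
#' @inheritParams log_likelihood_gaussian
#' @return `rss / n`.
#' @export
sigma2_ml <- function(rss, n) {
  stopifnot(rss >= 0, n >= 1)
  rss / n
}

#' Information criteria
#'
#' `AIC = -2 loglik + 2 p`, `BIC = -2 loglik + log(n) p`, where `p`
#' counts all estimated parameters.  Throughout the package `p` is the
#' number of regression coefficients plus one for the error variance.
#'
#' @param loglik Log-likelihood at the fit.
#' @param n_params_total Total number of estimated parameters `p`.
#' @param n Number of observations.
#' @param kind `"bic"` (default) or `"aic"`.
#' @return The criterion value (smaller is better).
#' @export
information_criterion <- function(loglik, n_params_total, n,
                                  kind = c("bic", "aic")) {
  kind <- match.arg(tolower(kind), c("bic", "aic"))
  stopifnot(n >= 1, n_params_total >= 1)
  pen <- if (kind == "aic") 2 else log(n)
  -2 * loglik + pen * n_params_total
}

# Collapse raw (x, y) observations to level sufficient statistics:
# distinct x levels, counts, level means, and the within-level sum of
# squares.  The least-squares fit depends on the data only through these.
as_level_data <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least two observations", call. = FALSE)
  ux <- sort(unique(x))
  idx <- match(x, ux)
  w <- tabulate(idx, nbins = length(ux))
  sums <- vapply(seq_along(ux), function(i) sum(y[idx == i]), numeric(1))
  ybar <- sums / w
  ssw <- sum(y^2) - sum(w * ybar^2)
  list(x = ux, w = w, ybar = ybar, ssw = max(ssw, 0), n = length(x),
       var_y = stats::var(y))
}

# variance floor for degenerate (zero-residual) fits, scaled to the data
sigma2_floor <- function(var_y) {
  .Machine$double.eps * (max(var_y, 0, na.rm = TRUE) + 1)
}

# Fast fitting path used everywhere (including the bootstrap loop):
# works on level statistics, returns a bare list.
fit_levels <- function(lev, family, bounds) {
  fam_code <- switch(family, emax = 1L, exponential = 2L, sigemax = 3L,
                     beta = 4L, 0L)
  if (fam_code == 0L) {
    # linear in all coefficients: weighted least squares on level means
    X <- if (family == "linear") cbind(1, lev$x) else cbind(1, lev$x, lev$x^2)
    fit <- stats::lm.wfit(X, lev$ybar, lev$w)
    theta <- unname(fit$coefficients)
    theta[is.na(theta)] <- 0
    mu <- drop(X %*% theta)
    rss_b <- sum(lev$w * (lev$ybar - mu)^2)
    res <- list(theta = theta, rss = lev$ssw + rss_b, converged = TRUE)
  } else {
    cf <- fit_profiled_cpp(lev$x, lev$w, lev$ybar, fam_code,
                           bounds$lower, bounds$upper,
                           if (is.na(bounds$scal)) 0 else bounds$scal,
                           bounds$n_grid)
    res <- list(theta = c(cf$b0, cf$b1, cf$nu),
                rss = lev$ssw + cf$rss_between,
                converged = isTRUE(cf$converged) && all(is.finite(c(cf$b0, cf$b1))))
  }
  res$n <- lev$n
  res$sigma2 <- res$rss / lev$n
  res
}

finish_fit <- function(res, family, lev, bounds, kind_n_params = NULL) {
  p_theta <- .family_npar[[family]]
  degenerate <- res$sigma2 < sigma2_floor(lev$var_y)
  s2 <- max(res$sigma2, sigma2_floor(lev$var_y))
  ll <- log_likelihood_gaussian(res$rss, lev$n, s2)
  p_tot <- p_theta + 1L
  list(
    family = family, theta = res$theta, scal = bounds$scal,
    rss = res$rss, sigma2 = res$sigma2, loglik = ll,
    aic = information_criterion(ll, p_tot, lev$n, "aic"),
    bic = information_criterion(ll, p_tot, lev$n, "bic"),
    n = lev$n, n_params = p_theta, converged = res$converged,
    degenerate = degenerate,
    identifiable = length(lev$x) >= p_theta
  )
}

#' Fit one candidate family to one group's data
#'
#' Ordinary least squares within the family's default parameter box:
#' families linear in all coefficients are solved in closed form; for the
#' nonlinear families the intercept and slope are profiled out and the
#' remaining one or two coefficients are optimized by a bounded grid scan
#' with local refinement.  The Gaussian log-likelihood is evaluated at the
#' least-squares coefficients with the ML variance `rss/n` (under
#' normality OLS and ML coincide), from which AIC and BIC follow with
#' parameter count `dim(theta) + 1`.
#'
#' @param data A data frame with the covariate and response columns.
#' @param family Candidate family name, see [curve_families()].
#' @param x,y Column names (strings) of covariate and response;
#'   defaults `"x"` and `"y"`.
#' @param dose_range Covariate range defining the fitting box; defaults to
#'   the observed range.
#' @param scal Fixed beta-family scale (default `1.2 * max(x)`); must
#'   exceed the largest design point.
#' @return An object of class `curve_fit`: a list with the coefficient
#'   vector `theta`, `rss`, ML variance `sigma2`, `loglik`, `aic`, `bic`,
#'   convergence/degeneracy flags and bookkeeping fields.  `tidy()` and
#'   `glance()` methods are available.
#' @examples
#' d <- simulate_curve_data(
#'   curve_params("emax", c(1, 2, 1)),
#'   curve_params("emax", c(1, 2, 1)),
#'   sigma2 = c(0.1, 0.1), n = c(20, 20), seed = 1
#' )
#' fit <- fit_curve(dplyr::filter(d, group == "1"), "emax")
#' glance(fit)
#' @export
fit_curve <- function(data, family, x = "x", y = "y",
                      dose_range = NULL, scal = NULL) {
  family <- match_family(family)
  xv <- data[[x]]; yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) {
    stop("columns '", x, "' and '", y, "' are required", call. = FALSE)
  }
  lev <- as_level_data(xv, yv)
  if (is.null(dose_range)) dose_range <- range(lev$x)
  bounds <- default_bounds(family, dose_range, scal)
  res <- fit_levels(lev, family, bounds)
  out <- finish_fit(res, family, lev, bounds)
  if (!out$identifiable) {
    warning(sprintf("family '%s': %d distinct levels < %d coefficients; fit may be unidentifiable",
                    family, length(lev$x), out$n_params), call. = FALSE)
  }
  out$dose_range <- dose_range
  class(out) <- "curve_fit"
  out
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit: %s>\n", x$family))
  cat("  theta:  ", paste(signif(x$theta, 5), collapse = ", "), "\n")
  cat(sprintf("  rss %.5g  sigma2 %.5g  loglik %.5g  BIC %.5g%s\n",
              x$rss, x$sigma2, x$loglik, x$bic,
              if (x$degenerate) "  [degenerate fit]" else ""))
  invisible(x)
}

#' Predicted mean curve of a fitted candidate
#' @param object A `curve_fit`.
#' @param x Numeric vector of covariate values.
#' @param ... Unused.
#' @return Numeric vector of fitted means.
#' @export
predict.curve_fit <- function(object, x, ...) {
  eval_curve_fast(object$family, object$theta, x,
                  if (is.na(object$scal)) NULL else object$scal)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.curve_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    term = paste0("b", seq_along(x$theta) - 1L),
    estimate = unname(x$theta)
  )
}

#' @export
glance.curve_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, rss = x$rss, sigma2 = x$sigma2,
    logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    nobs = x$n, converged = x$converged, degenerate = x$degenerate
  )
}
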