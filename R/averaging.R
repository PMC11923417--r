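#' Smooth information-criterion weights
#'
#' Softmax weights `w_k = exp(-I_k/2) / sum_j exp(-I_j/2)` over candidate
#' models, computed after subtracting the minimum criterion value so the
#' result is invariant under constant shifts and numerically stable.
#' Smaller criterion values give larger weights; candidates of equal total
#' parameter count receive identical AIC- and BIC-based weights because
#' the penalty then cancels.
#'
#' @param ic Numeric vector of information-criterion values, one per
#'   candidate (all finite).
#' @return Numeric weight vector on the simplex (sums to one).
#' @examples
#' smooth_weights(c(0, 2 * log(9)))  # c(0.9, 0.1)
#' @export
smooth_weights <- function(ic) {
  if (length(ic) < 1L) stop("need at least one candidate", call. = FALSE)
  bad <- !is.finite(ic)
  if (any(bad)) {
    stop("non-finite information criterion for candidate(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  e <- exp(-0.5 * (ic - min(ic)))
  e / sum(e)
}

# minimal averaged-fit builder on level statistics; hot-loop safe.
# families: character vector; bounds: precomputed list per family.
# Returns NULL if no candidate converges.
ma_fit_levels <- function(lev, families, bounds_list, scheme,
                          fixed_weights = NULL, ic_kind = NULL) {
  K <- length(families)
  fits <- vector("list", K)
  ok <- logical(K)
  for (k in seq_len(K)) {
    fits[[k]] <- fit_levels(lev, families[k], bounds_list[[k]])
    ok[k] <- fits[[k]]$converged
  }
  if (!any(ok)) return(NULL)
  w <- numeric(K)
  if (scheme == "fixed") {
    w <- fixed_weights
    if (!all(ok)) {
      w[!ok] <- 0
      if (sum(w) <= 0) return(NULL)
      w <- w / sum(w)
    }
  } else {
    floor_s2 <- sigma2_floor(lev$var_y)
    ic <- rep(Inf, K)
    for (k in seq_len(K)) {
      if (!ok[k]) next
      s2 <- max(fits[[k]]$sigma2, floor_s2)
      ll <- log_likelihood_gaussian(fits[[k]]$rss, lev$n, s2)
      p_tot <- .family_npar[[families[k]]] + 1L
      ic[k] <- information_criterion(ll, p_tot, lev$n, ic_kind)
    }
    w[ok] <- smooth_weights(ic[ok])
  }
  # averaged-curve residual variance (ML form) for bootstrap generation
  mu_lev <- numeric(length(lev$x))
  for (k in seq_len(K)) {
    if (w[k] == 0) next
    scal_k <- bounds_list[[k]]$scal
    mu_lev <- mu_lev + w[k] *
      eval_curve_fast(families[k], fits[[k]]$theta, lev$x,
                      if (is.na(scal_k)) NULL else scal_k)
  }
  sigma2 <- (lev$ssw + sum(lev$w * (lev$ybar - mu_lev)^2)) / lev$n
  list(families = families, fits = fits, weights = w, ok = ok,
       sigma2 = sigma2, mu_lev = mu_lev, n_dropped = sum(!ok))
}

#' Model-averaged fit for one group
#'
#' Fits every candidate family to the data by bounded least squares and
#' combines them into the averaged curve
#' `m(x) = sum_k w_k m_k(x, theta_k)`, with weights either smooth
#' BIC/AIC weights ([smooth_weights()]) or a fixed vector.  Candidates
#' that fail to converge are dropped and the weights renormalized; the
#' variance estimate used for parametric-bootstrap generation is the ML
#' variance of the averaged-curve residuals.
#'
#' @inheritParams fit_curve
#' @param families Character vector of candidate family names.
#' @param weights Weighting scheme: `"bic"` (default), `"aic"`, `"equal"`,
#'   or `"fixed"` (then supply `fixed_weights`).
#' @param fixed_weights Numeric simplex vector, one entry per family;
#'   required iff `weights = "fixed"`.
#' @return An object of class `ma_fit` with per-candidate `curve_fit`s,
#'   the weight vector, the pooled variance `sigma2`, and the data.
#'   Methods: `predict()`, `tidy()` (one row per candidate), `glance()`,
#'   `autoplot()`.
#' @examples
#' d <- simulate_curve_data(
#'   curve_params("emax", c(1, 2, 1)),
#'   curve_params("exponential", c(0.25, 2.2, 8)),
#'   sigma2 = c(0.25, 0.25), n = c(50, 50), seed = 7
#' )
#' fit <- ma_fit(dplyr::filter(d, group == "1"),
#'               families = c("emax", "exponential"))
#' tidy(fit)
#' @export
ma_fit <- function(data, families = c("emax", "exponential"),
                   weights = c("bic", "aic", "equal", "fixed"),
                   fixed_weights = NULL, x = "x", y = "y",
                   dose_range = NULL, scal = NULL) {
  weights <- match.arg(weights)
  families <- match_family(families)
  if (length(families) < 1L) stop("need at least one candidate family",
                                  call. = FALSE)
  scheme <- switch(weights, bic = "smooth_bic", aic = "smooth_aic",
                   equal = "fixed", fixed = "fixed")
  if (weights == "equal") fixed_weights <- rep(1 / length(families),
                                               length(families))
  if (scheme == "fixed") {
    if (is.null(fixed_weights) || length(fixed_weights) != length(families) ||
        any(fixed_weights < 0) || abs(sum(fixed_weights) - 1) > 1e-8) {
      stop("fixed_weights must be a simplex vector matching 'families'",
           call. = FALSE)
    }
  }
  xv <- data[[x]]; yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) {
    stop("columns '", x, "' and '", y, "' are required", call. = FALSE)
  }
  lev <- as_level_data(xv, yv)
  if (is.null(dose_range)) dose_range <- range(lev$x)
  bounds_list <- lapply(families, default_bounds, dose_range = dose_range,
                        scal = scal)
  ic_kind <- if (weights == "aic") "aic" else "bic"
  core <- ma_fit_levels(lev, families, bounds_list, scheme,
                        fixed_weights, ic_kind)
  if (is.null(core)) {
    stop("no candidate model converged", call. = FALSE)
  }
  fits <- lapply(seq_along(families), function(k) {
    out <- finish_fit(core$fits[[k]], families[k], lev, bounds_list[[k]])
    out$dose_range <- dose_range
    class(out) <- "curve_fit"
    out
  })
  structure(list(
    families = families, fits = fits,
    weights = stats::setNames(core$weights, families),
    scheme = switch(weights, bic = "smooth_bic", aic = "smooth_aic",
                    equal = "fixed_equal", fixed = "fixed"),
    sigma2 = core$sigma2, lev = lev, n = lev$n,
    dose_range = dose_range, bounds_list = bounds_list,
    n_dropped = core$n_dropped,
    data = tibble::tibble(x = xv, y = yv)
  ), class = "ma_fit")
}

# averaged curve evaluation
averaged_predict <- function(avg, x) {
  out <- numeric(length(x))
  for (k in seq_along(avg$families)) {
    if (avg$weights[k] == 0) next
    f <- avg$fits[[k]]
    out <- out + avg$weights[k] *
      eval_curve_fast(f$family, f$theta, x,
                      if (is.na(f$scal)) NULL else f$scal)
  }
  out
}

#' @export
#' @rdname ma_fit
#' @param object,... Method arguments.
#' @param newdata Optional data frame with an `x` column; alternatively
#'   pass a numeric vector via `x`.
predict.ma_fit <- function(object, newdata = NULL, x = NULL, ...) {
  if (is.null(x)) {
    x <- if (is.null(newdata)) object$data$x else newdata[["x"]]
  }
  averaged_predict(object, x)
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("<ma_fit: %d candidates, scheme %s, n = %d>\n",
              length(x$families), x$scheme, x$n))
  w <- signif(x$weights, 4)
  cat("  weights:", paste(sprintf("%s=%s", names(w), w), collapse = "  "), "\n")
  cat(sprintf("  sigma2 (averaged-curve residuals): %.5g\n", x$sigma2))
  invisible(x)
}

#' @export
tidy.ma_fit <- function(x, ...) {
  dplyr::mutate(
    purrr::map_dfr(x$fits, glance),
    weight = unname(x$weights), .after = "family"
  )
}

#' @export
glance.ma_fit <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$families), scheme = x$scheme,
    sigma2 = x$sigma2, nobs = x$n, n_dropped = x$n_dropped,
    top_family = x$families[which.max(x$weights)],
    top_weight = max(x$weights)
  )
}
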