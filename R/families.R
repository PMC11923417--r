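#' Candidate regression families
#'
#' The package models the mean response of each group by one of six
#' candidate families that are standard in dose-response (and, by direct
#' transfer, time-response) modelling:
#'
#' * `linear`:       `m(x) = b0 + b1 * x`
#' * `quadratic`:    `m(x) = b0 + b1 * x + b2 * x^2`
#' * `emax`:         `m(x) = b0 + b1 * x / (b2 + x)`
#' * `exponential`:  `m(x) = b0 + b1 * (exp(x / b2) - 1)`
#' * `sigemax`:      `m(x) = b0 + b1 * x^b3 / (b2^b3 + x^b3)` (Hill model)
#' * `beta`:         `m(x) = b0 + b1 * B(b2, b3) * (x/s)^b2 * (1 - x/s)^b3`
#'   with `B(b2, b3) = (b2 + b3)^(b2 + b3) / (b2^b2 * b3^b3)` and a fixed
#'   scale `s` exceeding the largest design point (default `1.2 * max(x)`).
#'
#' All families are twice continuously differentiable on the design range,
#' the coefficient vector is ordered as printed above, and `b2` of `emax`,
#' `sigemax` and `beta` as well as `b3` of `sigemax`/`beta` must be
#' strictly positive; `b2` of `exponential` must be nonzero.
#'
#' @return `curve_families()` returns the character vector of the six
#'   family names in canonical order.
#' @examples
#' curve_families()
#' eval_curve("emax", c(1, 2, 1), x = 0:4)
#' @export
curve_families <- function() {
  c("linear", "quadratic", "emax", "exponential", "sigemax", "beta")
}

# number of regression coefficients per family
.family_npar <- c(
  linear = 2L, quadratic = 3L, emax = 3L, exponential = 3L,
  sigemax = 4L, beta = 4L
)

#' @rdname curve_families
#' @param family Family name (one of `curve_families()`, case-insensitive;
#'   `"sigEmax"` is accepted as an alias of `"sigemax"`).
#' @export
n_params <- function(family) {
  family <- match_family(family)
  unname(.family_npar[family])
}

match_family <- function(family) {
  fam <- tolower(as.character(family))
  ok <- fam %in% names(.family_npar)
  if (!all(ok)) {
    stop("unknown model family: ", paste(unique(fam[!ok]), collapse = ", "),
         " (must be one of ", paste(names(.family_npar), collapse = ", "), ")",
         call. = FALSE)
  }
  fam
}

check_theta <- function(family, theta, scal = NULL) {
  family <- match_family(family)
  p <- .family_npar[[family]]
  if (length(theta) != p) {
    stop(sprintf("family '%s' needs %d coefficients, got %d",
                 family, p, length(theta)), call. = FALSE)
  }
  if (any(!is.finite(theta))) {
    stop(sprintf("family '%s': non-finite coefficient", family), call. = FALSE)
  }
  bad <- switch(family,
    emax        = if (theta[3] <= 0) "b2 (ED50) must be > 0",
    exponential = if (theta[3] == 0) "b2 (rate scale) must be nonzero",
    sigemax     = if (theta[3] <= 0) "b2 (ED50) must be > 0"
                  else if (theta[4] <= 0) "b3 (Hill exponent) must be > 0",
    beta        = if (theta[3] <= 0) "b2 (delta1) must be > 0"
                  else if (theta[4] <= 0) "b3 (delta2) must be > 0",
    NULL
  )
  if (!is.null(bad)) {
    stop(sprintf("invalid parameter for family '%s': %s", family, bad),
         call. = FALSE)
  }
  if (family == "beta") {
    if (is.null(scal) || !is.finite(scal) || scal <= 0) {
      stop("beta family requires a positive fixed scale 'scal'", call. = FALSE)
    }
  }
  invisible(family)
}

#' Evaluate a candidate mean curve
#'
#' Computes the mean response `m(x, theta)` of one candidate family at a
#' vector of covariate values.  Evaluation outside the design range is
#' permitted (bootstrap and plotting may probe slightly outside), except
#' where the formula itself is undefined: the beta family is only defined
#' for `0 <= x <= scal`.
#'
#' @param family Family name, see [curve_families()].
#' @param theta Coefficient vector in the family's canonical order.
#' @param x Numeric vector of covariate values (dose or time).
#' @param scal Fixed scale of the beta family (ignored otherwise).
#' @return Numeric vector of mean responses, same length as `x`.
#' @export
eval_curve <- function(family, theta, x, scal = NULL) {
  family <- match_family(family)
  check_theta(family, theta, scal)
  if (family == "beta" && any(x < 0 | x > scal)) {
    stop("beta family is undefined outside [0, scal]", call. = FALSE)
  }
  eval_curve_fast(family, theta, x, scal)
}

# no-validation evaluation used in the bootstrap hot loop
eval_curve_fast <- function(family, theta, x, scal = NULL) {
  switch(family,
    linear      = theta[1] + theta[2] * x,
    quadratic   = theta[1] + theta[2] * x + theta[3] * x^2,
    emax        = theta[1] + theta[2] * x / (theta[3] + x),
    exponential = theta[1] + theta[2] * (exp(x / theta[3]) - 1),
    sigemax     = {
      xh <- x^theta[4]
      theta[1] + theta[2] * xh / (theta[3]^theta[4] + xh)
    },
    beta = {
      d1 <- theta[3]; d2 <- theta[4]
      bnorm <- (d1 + d2)^(d1 + d2) / (d1^d1 * d2^d2)
      z <- pmin(pmax(x / scal, 0), 1)
      theta[1] + theta[2] * bnorm * z^d1 * (1 - z)^d2
    }
  )
}

#' Default fitting box and starting grid for a family
#'
#' Returns box bounds for the nonlinear coefficients of a family, scaled
#' to the design range, together with a grid of starting values used for
#' multi-start optimization.  Families that are linear in all coefficients
#' (linear, quadratic) have no nonlinear coefficients and are fitted in
#' closed form.
#'
#' @param family Family name.
#' @param dose_range Length-2 numeric, the covariate range `[lower, upper]`.
#' @param scal Optional fixed beta-model scale; defaults to
#'   `1.2 * dose_range[2]`.
#' @return A list with elements `lower`, `upper` (numeric vectors, empty
#'   for linear/quadratic), `scal` (beta only, else `NA`), and `n_grid`
#'   (starting-grid resolution per nonlinear coefficient).
#' @export
default_bounds <- function(family, dose_range, scal = NULL) {
  family <- match_family(family)
  stopifnot(length(dose_range) == 2, dose_range[1] < dose_range[2])
  umax <- dose_range[2]
  if (is.null(scal)) scal <- 1.2 * umax
  out <- switch(family,
    linear      = list(lower = numeric(0), upper = numeric(0)),
    quadratic   = list(lower = numeric(0), upper = numeric(0)),
    emax        = list(lower = 0.001 * umax, upper = 1.5 * umax),
    exponential = list(lower = 0.05 * umax, upper = 3 * umax),
    sigemax     = list(lower = c(0.001 * umax, 0.5), upper = c(1.5 * umax, 10)),
    beta        = list(lower = c(0.05, 0.05), upper = c(4, 4))
  )
  out$scal <- if (family == "beta") scal else NA_real_
  out$n_grid <- if (length(out$lower) == 2L) 12L else 30L
  out
}
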