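#' Specify a candidate curve by family and coefficients
#'
#' A lightweight container pairing a family name with a coefficient
#' vector (and, for the beta family, its fixed scale).  Used to define
#' true curves for data generation and to compare known curves with
#' [max_abs_deviation()].
#'
#' @param family Family name, see [curve_families()].
#' @param theta Coefficient vector in canonical order.
#' @param scal Fixed beta-family scale (required for `"beta"`).
#' @return An object of class `curve_params`.
#' @examples
#' curve_params("emax", c(1, 2, 1))
#' @export
curve_params <- function(family, theta, scal = NULL) {
  family <- match_family(family)
  check_theta(family, theta, scal)
  structure(list(family = family, theta = as.numeric(theta),
                 scal = if (is.null(scal)) NA_real_ else scal),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("<curve_params: %s(%s)%s>\n", x$family,
              paste(signif(x$theta, 5), collapse = ", "),
              if (!is.na(x$scal)) sprintf(", scal=%g", x$scal) else ""))
  invisible(x)
}

#' @export
predict.curve_params <- function(object, x, ...) {
  eval_curve(object$family, object$theta, x,
             if (is.na(object$scal)) NULL else object$scal)
}

# coerce the things that can stand for a curve into a plain function of x
as_curve_fun <- function(object) {
  if (inherits(object, "curve_params") || inherits(object, "curve_fit")) {
    family <- object$family; theta <- object$theta
    scal <- if (is.na(object$scal)) NULL else object$scal
    function(x) eval_curve_fast(family, theta, x, scal)
  } else if (inherits(object, "ma_fit")) {
    function(x) averaged_predict(object, x)
  } else if (is.function(object)) {
    object
  } else {
    stop("cannot interpret object of class ",
         paste(class(object), collapse = "/"), " as a curve", call. = FALSE)
  }
}
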