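#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a model-averaged fit
#'
#' Data points, the individual candidate curves (weight-coded
#' transparency) and the averaged curve.
#'
#' @param object An [ma_fit()] object.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ma_fit <- function(object, n_grid = 200L, ...) {
  xs <- seq(object$dose_range[1], object$dose_range[2], length.out = n_grid)
  cand <- purrr::map2_dfr(object$fits, object$weights, function(f, w) {
    tibble::tibble(x = xs, y = predict(f, xs), family = f$family, weight = w)
  })
  avg <- tibble::tibble(x = xs, y = averaged_predict(object, xs))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = cand,
                       ggplot2::aes(colour = .data$family,
                                    alpha = .data$weight)) +
    ggplot2::geom_line(data = avg, linewidth = 1) +
    ggplot2::scale_alpha(range = c(0.15, 1), limits = c(0, 1)) +
    ggplot2::labs(y = "response", x = "covariate",
                  title = "Candidate curves and averaged fit",
                  alpha = "weight") +
    ggplot2::theme_minimal()
}

#' Plot an equivalence test
#'
#' Both groups' data and averaged curves, with the location of the
#' maximal absolute deviation marked and the margin/bound reported in the
#' subtitle.
#'
#' @param object An [equiv_test()] object.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.equiv_test <- function(object, n_grid = 200L, ...) {
  xs <- seq(object$dose_range[1], object$dose_range[2], length.out = n_grid)
  curves <- purrr::map2_dfr(object$fits, object$groups, function(f, g) {
    tibble::tibble(x = xs, y = averaged_predict(f, xs), group = g)
  })
  pts <- purrr::map2_dfr(object$fits, object$groups, function(f, g) {
    dplyr::mutate(f$data, group = g)
  })
  seg <- tibble::tibble(
    x = object$x_at_max,
    y1 = averaged_predict(object$fits[[1]], object$x_at_max),
    y2 = averaged_predict(object$fits[[2]], object$x_at_max)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = curves, linewidth = 1) +
    ggplot2::geom_segment(data = seg, inherit.aes = FALSE, linetype = 2,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$y1, yend = .data$y2)) +
    ggplot2::labs(
      x = "covariate", y = "response",
      title = "Model-averaged equivalence test",
      subtitle = sprintf(
        "d_hat = %.3g, %s bound u = %.3g, margin = %.3g: %s",
        object$d_hat, object$ci, object$u, object$epsilon_used,
        if (object$reject) "equivalent" else "not shown equivalent")
    ) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates from a simulation sweep
#'
#' Rejection rate against the true deviation, one line per model
#' specification, with the nominal level marked.
#'
#' @param sweep Tibble from [run_scenario_sweep()].
#' @return A ggplot.
#' @export
plot_rejection_rates <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$d_true, y = .data$rate,
                                      colour = .data$specification)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = unique(sweep$alpha), linetype = 3) +
    ggplot2::labs(x = "true maximal deviation d", y = "rejection rate") +
    ggplot2::theme_minimal()
}
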