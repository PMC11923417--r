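#' Maximal absolute deviation between two curves
#'
#' Computes `d = max over x in [lower, upper] of |m1(x) - m2(x)|` by a
#' dense equispaced grid scan (default 1001 points) followed by bounded
#' local refinement around the best grid points.  Ties are broken towards
#' the smallest `x`.
#'
#' @param curve1,curve2 Curves to compare: [curve_params()],
#'   `curve_fit`, `ma_fit` objects, or plain functions of `x`.
#' @param dose_range Length-2 numeric range to maximize over.  Defaults to
#'   the fitted range when both curves are fitted objects.
#' @param n_grid Grid resolution (default 1001).
#' @return A list with `d` (the maximal absolute deviation) and
#'   `x_at_max` (a covariate value attaining it).
#' @examples
#' max_abs_deviation(curve_params("emax", c(1, 2, 1)),
#'                   curve_params("exponential", c(0.25, 2.2, 8)),
#'                   dose_range = c(0, 4))$d
#' @export
max_abs_deviation <- function(curve1, curve2, dose_range = NULL,
                              n_grid = 1001L) {
  if (is.null(dose_range)) {
    dr1 <- curve1$dose_range; dr2 <- curve2$dose_range
    if (is.null(dr1) || is.null(dr2)) {
      stop("dose_range is required unless both curves are fitted objects",
           call. = FALSE)
    }
    dose_range <- c(max(dr1[1], dr2[1]), min(dr1[2], dr2[2]))
  }
  f1 <- as_curve_fun(curve1)
  f2 <- as_curve_fun(curve2)
  max_dev_fun(f1, f2, dose_range[1], dose_range[2], n_grid)
}

# Grid scan + staged local refinement on |f1 - f2|.  Refinement zooms a
# 41-point window three times around each of the top grid points (skipping
# neighbours of an already-chosen centre), which localizes the maximum to
# ~1e-7 of the range with a handful of vectorized evaluations.  Ties break
# towards the smallest x.
max_dev_fun <- function(f1, f2, lower, upper, n_grid = 1001L, xs = NULL) {
  if (is.null(xs)) xs <- seq(lower, upper, length.out = n_grid)
  frac41 <- (0:40) / 40
  dif <- abs(f1(xs) - f2(xs))
  ord <- order(dif, decreasing = TRUE)
  centers <- integer(0)
  for (i in ord) {
    if (all(abs(i - centers) > 1L)) centers <- c(centers, i)
    if (length(centers) == 3L) break
  }
  h <- (xs[2] - xs[1])
  best_d <- dif[centers[1]]
  best_x <- xs[centers[1]]
  for (ci in centers) {
    lo <- max(lower, xs[ci] - h)
    hi <- min(upper, xs[ci] + h)
    for (stage in 1:3) {
      xl <- lo + (hi - lo) * frac41
      dl <- abs(f1(xl) - f2(xl))
      j <- which.max(dl)
      w <- (hi - lo) / 40
      lo <- max(lower, xl[j] - w)
      hi <- min(upper, xl[j] + w)
    }
    if (dl[j] > best_d + 1e-15 ||
        (dl[j] >= best_d - 1e-15 && xl[j] < best_x)) {
      best_d <- dl[j]
      best_x <- xl[j]
    }
  }
  list(d = best_d, x_at_max = best_x)
}

#' Upper confidence bounds from a bootstrap sample
#'
#' `percentile_upper_bound()` returns the order statistic at (1-based)
#' index `floor(n_boot * (1 - alpha))` of the sorted bootstrap sample —
#' the upper end of the one-sided percentile bootstrap confidence
#' interval.  `hybrid_upper_bound()` instead uses the asymptotic
#' normality of the statistic: `u = d_hat + se_hat * z_(1-alpha)` where
#' `se_hat` is the empirical standard deviation of the bootstrap sample.
#'
#' @param boot_sample Numeric vector of bootstrap statistics.
#' @param alpha One-sided significance level in (0, 0.5).
#' @param d_hat The observed statistic (hybrid bound only).
#' @return `percentile_upper_bound()`: the bound `u`.
#'   `hybrid_upper_bound()`: list with `u` and `se_hat`.
#' @export
percentile_upper_bound <- function(boot_sample, alpha) {
  stopifnot(length(boot_sample) >= 1)
  s <- sort(boot_sample)
  idx <- max(1L, min(length(s), floor(length(s) * (1 - alpha))))
  s[idx]
}

#' @rdname percentile_upper_bound
#' @export
hybrid_upper_bound <- function(d_hat, boot_sample, alpha) {
  stopifnot(length(boot_sample) >= 2)
  se_hat <- stats::sd(boot_sample)
  list(u = d_hat + se_hat * stats::qnorm(1 - alpha), se_hat = se_hat)
}

#' Equivalence decision rule
#'
#' Conclude equivalence (reject `H0: d >= epsilon`) iff the margin
#' strictly exceeds the upper confidence bound: `epsilon > u`.
#'
#' @param epsilon Equivalence margin (> 0).
#' @param u Upper confidence bound for the maximal deviation.
#' @return Logical flag.
#' @export
decide_equivalence <- function(epsilon, u) {
  stopifnot(epsilon > 0, u >= 0)
  epsilon > u
}

#' Resolve a range-relative equivalence margin
#'
#' When responses live on scales that differ across analyses (e.g. log2
#' expression of different genes), the margin is specified as a fraction
#' `epsilon_rel` of the range of the fitted response values of both
#' groups: `epsilon = epsilon_rel * (max yhat - min yhat)`.
#'
#' @param fitted_values Pooled fitted values of both groups' averaged
#'   curves at their design points.
#' @param epsilon_rel Fraction in (0, 1).
#' @return The absolute margin.
#' @export
relative_threshold <- function(fitted_values, epsilon_rel) {
  stopifnot(epsilon_rel > 0, epsilon_rel < 1)
  rng <- max(fitted_values) - min(fitted_values)
  if (rng <= 0) stop("fitted-value range is zero; relative threshold undefined",
                     call. = FALSE)
  epsilon_rel * rng
}

# deterministic substream seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + i) %% 2147483629)
}

# One parametric-bootstrap replicate: regenerate Gaussian responses around
# the averaged fitted level means, refit and reweight all candidates per
# group exactly as in the original analysis, and return the replicated
# maximal-deviation statistic (NA if a group loses all candidates).
boot_once <- function(g1, g2, lower, upper, n_grid, xs = NULL) {
  cores <- vector("list", 2L)
  for (gi in 1:2) {
    g <- if (gi == 1L) g1 else g2
    lev <- g$lev
    sd_l <- sqrt(max(g$core$sigma2, 0))
    y <- rep(g$core$mu_lev, lev$w) + stats::rnorm(lev$n, 0, sd_l)
    # levels are stored contiguously, so level sums are segment sums
    cs <- cumsum(y)
    ends <- cumsum(lev$w)
    sums <- diff(c(0, cs[ends]))
    ybar <- sums / lev$w
    ssw <- max(sum(y^2) - sum(lev$w * ybar^2), 0)
    tot <- sum(sums)
    var_y <- (ssw + sum(lev$w * ybar^2) - tot^2 / lev$n) /
      max(lev$n - 1L, 1L)
    lev_b <- list(x = lev$x, w = lev$w, ybar = ybar, ssw = ssw,
                  n = lev$n, var_y = var_y)
    core_b <- ma_fit_levels(lev_b, g$families, g$bounds_list, g$scheme,
                            g$fixed_weights, g$ic_kind)
    if (is.null(core_b)) return(NULL)
    cores[[gi]] <- core_b
  }
  f1 <- make_avg_fun(cores[[1]], g1)
  f2 <- make_avg_fun(cores[[2]], g2)
  dev <- max_dev_fun(f1, f2, lower, upper, n_grid, xs = xs)
  list(d = dev$d, dropped = cores[[1]]$n_dropped + cores[[2]]$n_dropped)
}

make_avg_fun <- function(core, g) {
  families <- core$families
  weights <- core$weights
  thetas <- lapply(core$fits, `[[`, "theta")
  scals <- vapply(g$bounds_list, `[[`, numeric(1), "scal")
  function(x) {
    out <- numeric(length(x))
    for (k in seq_along(families)) {
      if (weights[k] == 0) next
      out <- out + weights[k] *
        eval_curve_fast(families[k], thetas[[k]], x,
                        if (is.na(scals[k])) NULL else scals[k])
    }
    out
  }
}

# group descriptor used by the bootstrap, built from an ma_fit
as_boot_group <- function(avg) {
  list(
    lev = avg$lev,
    core = list(sigma2 = avg$sigma2,
                mu_lev = averaged_predict(avg, avg$lev$x)),
    families = avg$families,
    bounds_list = avg$bounds_list,
    scheme = if (avg$scheme %in% c("fixed", "fixed_equal")) "fixed" else avg$scheme,
    fixed_weights = if (avg$scheme %in% c("fixed", "fixed_equal"))
      unname(avg$weights) else NULL,
    ic_kind = if (avg$scheme == "smooth_aic") "aic" else "bic"
  )
}

#' Parametric bootstrap sample of the maximal-deviation statistic
#'
#' Draws `n_boot` replicates: for each group, responses are regenerated
#' as Gaussian around the averaged fitted means at the original design
#' points with the group's ML residual variance, all candidates are
#' refitted and reweighted, and the maximal absolute deviation between
#' the two replicated averaged curves is recorded.  Replicates in which a
#' group loses every candidate are redrawn (at most 10 attempts each).
#'
#' @param avg1,avg2 Per-group [ma_fit()] objects.
#' @param n_boot Number of bootstrap replicates.
#' @param alpha Unused here; part of the test wrapper.
#' @param dose_range Range over which the deviation is maximized
#'   (default: intersection of the two fitted ranges).
#' @param n_grid Deviation grid resolution.
#' @param seed Integer master seed (replicate substreams are derived from
#'   it, so results do not depend on execution order).
#' @return Numeric vector of `n_boot` nonnegative deviations, with
#'   attributes `n_dropped` (candidate fits dropped for non-convergence)
#'   and `n_redrawn` (replicates regenerated).
#' @export
parametric_bootstrap <- function(avg1, avg2, n_boot = 500L, alpha = 0.05,
                                 dose_range = NULL, n_grid = 1001L,
                                 seed = NULL) {
  if (is.null(dose_range)) {
    dose_range <- c(max(avg1$dose_range[1], avg2$dose_range[1]),
                    min(avg1$dose_range[2], avg2$dose_range[2]))
  }
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  g1 <- as_boot_group(avg1)
  g2 <- as_boot_group(avg2)
  # The deviation statistic is symmetric in the two groups; make the
  # bootstrap exactly so by ordering the groups' noise substreams by a
  # data fingerprint rather than by input order.
  key <- function(g) paste(format(c(g$lev$n, g$lev$x, g$lev$ybar,
                                    g$core$sigma2), digits = 15),
                           collapse = ",")
  if (key(g2) < key(g1)) { tmp <- g1; g1 <- g2; g2 <- tmp }
  out <- numeric(n_boot)
  dropped <- 0L
  redrawn <- 0L
  xs <- seq(dose_range[1], dose_range[2], length.out = n_grid)
  for (b in seq_len(n_boot)) {
    res <- NULL
    for (attempt in 0:10) {
      set.seed(derive_seed(seed, b + 1000003L * attempt))
      res <- boot_once(g1, g2, dose_range[1], dose_range[2], n_grid, xs = xs)
      if (!is.null(res)) break
      redrawn <- redrawn + 1L
    }
    if (is.null(res)) {
      stop("bootstrap replicate failed repeatedly: no candidate model converged",
           call. = FALSE)
    }
    out[b] <- res$d
    dropped <- dropped + res$dropped
  }
  attr(out, "n_dropped") <- dropped
  attr(out, "n_redrawn") <- redrawn
  out
}

#' Model-averaged equivalence test for two regression curves
#'
#' Tests `H0: d >= epsilon` against `H1: d < epsilon`, where `d` is the
#' maximal absolute deviation between the two groups' mean curves over
#' the covariate range.  Each group's curve is estimated by model
#' averaging over the candidate families ([ma_fit()]); the upper
#' confidence bound for `d` comes from a parametric bootstrap, either as
#' a percentile bound or as the hybrid normal-approximation bound
#' `d_hat + z * se_hat`.  Equivalence is concluded iff
#' `epsilon > u` (confidence-interval duality; an alpha-level test).
#'
#' @param data Long-format data frame with group, covariate and response
#'   columns; exactly two distinct groups.
#' @param families Candidate families per group: a character vector
#'   (same set for both groups) or a list of two character vectors.
#' @param weights Weighting scheme, see [ma_fit()].
#' @param fixed_weights Simplex vector for `weights = "fixed"`.
#' @param epsilon Absolute equivalence margin; give exactly one of
#'   `epsilon` and `epsilon_rel`.
#' @param epsilon_rel Margin as a fraction of the range of the fitted
#'   response values of both groups ([relative_threshold()]).
#' @param alpha Significance level in (0, 0.5); default 0.05.
#' @param n_boot Bootstrap replicates; default 500.
#' @param ci `"hybrid"` (default) or `"percentile"`.
#' @param group,x,y Column names in `data`.
#' @param dose_range Range over which to maximize (default: intersection
#'   of the groups' observed ranges).
#' @param scal Fixed beta-family scale.
#' @param n_grid Deviation grid resolution.
#' @param seed Integer master seed for the bootstrap.
#' @return Object of class `equiv_test`; use `glance()` for a one-row
#'   summary, `tidy()` for per-candidate weights, `autoplot()` for a
#'   picture.  Fields include `d_hat`, `boot_sample`, `u`, `se_hat`,
#'   `epsilon_used`, `u_scaled` (when `epsilon_rel` is used) and
#'   `reject`.
#' @examples
#' d <- simulate_curve_data(
#'   curve_params("emax", c(1, 2, 1)),
#'   curve_params("emax", c(1, 2, 1)),
#'   sigma2 = c(0.05, 0.05), n = c(25, 25), seed = 3
#' )
#' tst <- equiv_test(d, families = c("emax", "exponential"),
#'                   epsilon = 1, n_boot = 100, seed = 4)
#' glance(tst)
#' @export
equiv_test <- function(data, families = c("emax", "exponential"),
                       weights = c("bic", "aic", "equal", "fixed"),
                       fixed_weights = NULL,
                       epsilon = NULL, epsilon_rel = NULL,
                       alpha = 0.05, n_boot = 500L,
                       ci = c("hybrid", "percentile"),
                       group = "group", x = "x", y = "y",
                       dose_range = NULL, scal = NULL,
                       n_grid = 1001L, seed = NULL) {
  ci <- match.arg(ci)
  weights <- match.arg(weights)
  if (is.null(epsilon) == is.null(epsilon_rel)) {
    stop("give exactly one of 'epsilon' and 'epsilon_rel'", call. = FALSE)
  }
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be > 0",
                                              call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)",
                                       call. = FALSE)
  gv <- data[[group]]
  if (is.null(gv)) stop("column '", group, "' is required", call. = FALSE)
  glev <- if (is.factor(gv)) levels(droplevels(gv)) else sort(unique(gv))
  if (length(glev) != 2L) {
    stop("exactly two groups required, found ", length(glev), call. = FALSE)
  }
  fam_list <- if (is.list(families)) families else list(families, families)
  if (length(fam_list) != 2L) stop("'families' must be one set or a list of two",
                                   call. = FALSE)

  avg <- vector("list", 2L)
  for (gi in 1:2) {
    di <- data[gv == glev[gi], , drop = FALSE]
    avg[[gi]] <- ma_fit(di, families = fam_list[[gi]], weights = weights,
                        fixed_weights = fixed_weights, x = x, y = y,
                        dose_range = dose_range, scal = scal)
  }
  if (is.null(dose_range)) {
    dose_range <- c(max(avg[[1]]$dose_range[1], avg[[2]]$dose_range[1]),
                    min(avg[[1]]$dose_range[2], avg[[2]]$dose_range[2]))
  }

  dev <- max_dev_fun(as_curve_fun(avg[[1]]), as_curve_fun(avg[[2]]),
                     dose_range[1], dose_range[2], n_grid)
  d_hat <- dev$d

  boot <- parametric_bootstrap(avg[[1]], avg[[2]], n_boot = n_boot,
                               dose_range = dose_range, n_grid = n_grid,
                               seed = seed)
  if (ci == "percentile") {
    u <- percentile_upper_bound(boot, alpha)
    se_hat <- stats::sd(boot)
  } else {
    hb <- hybrid_upper_bound(d_hat, boot, alpha)
    u <- hb$u
    se_hat <- hb$se_hat
  }

  fitted_vals <- c(averaged_predict(avg[[1]], avg[[1]]$lev$x),
                   averaged_predict(avg[[2]], avg[[2]]$lev$x))
  yrange <- max(fitted_vals) - min(fitted_vals)
  if (is.null(epsilon)) {
    epsilon_used <- relative_threshold(fitted_vals, epsilon_rel)
    u_scaled <- u / yrange
  } else {
    epsilon_used <- epsilon
    u_scaled <- NA_real_
  }
  structure(list(
    d_hat = d_hat, x_at_max = dev$x_at_max, boot_sample = as.numeric(boot),
    u = u, se_hat = se_hat, epsilon = epsilon, epsilon_rel = epsilon_rel,
    epsilon_used = epsilon_used, u_scaled = u_scaled,
    reject = decide_equivalence(epsilon_used, u),
    alpha = alpha, n_boot = n_boot, ci = ci,
    groups = as.character(glev), fits = avg, dose_range = dose_range,
    fitted_range = yrange, seed = seed,
    n_dropped = attr(boot, "n_dropped"), n_redrawn = attr(boot, "n_redrawn")
  ), class = "equiv_test")
}

#' @export
print.equiv_test <- function(x, ...) {
  cat("<equiv_test: maximal-deviation equivalence test>\n")
  cat(sprintf("  groups: %s vs %s   range [%g, %g]\n",
              x$groups[1], x$groups[2], x$dose_range[1], x$dose_range[2]))
  cat(sprintf("  d_hat = %.4g (at x = %.3g)   %s upper bound u = %.4g\n",
              x$d_hat, x$x_at_max, x$ci, x$u))
  if (!is.null(x$epsilon_rel)) {
    cat(sprintf("  margin: %.3g (= %.3g of fitted range %.4g); u_scaled = %.4g\n",
                x$epsilon_used, x$epsilon_rel, x$fitted_range, x$u_scaled))
  } else {
    cat(sprintf("  margin: epsilon = %.4g\n", x$epsilon_used))
  }
  cat(sprintf("  decision (alpha = %g): %s\n", x$alpha,
              if (x$reject) "reject H0 -- curves equivalent"
              else "fail to reject H0 -- equivalence not shown"))
  invisible(x)
}

#' @export
glance.equiv_test <- function(x, ...) {
  tibble::tibble(
    d_hat = x$d_hat, se_hat = x$se_hat, u = x$u,
    epsilon = x$epsilon_used,
    epsilon_rel = x$epsilon_rel %||% NA_real_,
    u_scaled = x$u_scaled, reject = x$reject,
    alpha = x$alpha, n_boot = x$n_boot, ci = x$ci,
    n_dropped = x$n_dropped, n_redrawn = x$n_redrawn
  )
}

#' @export
tidy.equiv_test <- function(x, ...) {
  purrr::map2_dfr(x$fits, x$groups, function(f, g) {
    dplyr::mutate(tidy(f), group = g, .before = 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
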