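#' True curves of the three simulation scenarios
#'
#' The benchmark scenarios on the dose range `[0, 4]`:
#'
#' 1. emax `theta1 = (1, 2, 1)` versus exponential
#'    `theta2 = (b20, 2.2, 8)` with `b20` in
#'    `{0.25, 0.5, 0.75, 1, 1.5}`, giving true maximal deviations
#'    `{1.5, 1.25, 1, 0.75, 0.5}`;
#' 2. two shifted emax curves `(b10, 5, 1)` vs `(0, 5, 1)`, so the
#'    deviation is constant in `x` and equals `b10`;
#' 3. two shifted exponential curves `(b10, 2.2, 8)` vs `(0, 2.2, 8)`,
#'    again with deviation `b10` everywhere.
#'
#' @param scenario Scenario id, 1, 2 or 3.
#' @param level_param Scenario-1 `b20`, or the shift `b10` for
#'   scenarios 2-3.
#' @return A list with `params1`, `params2` ([curve_params()]) and the
#'   implied true deviation `d_true` (computed by [max_abs_deviation()]
#'   for scenario 1; exactly `level_param` otherwise).
#' @export
scenario_truth <- function(scenario, level_param) {
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3", call. = FALSE)
  if (scenario == 1) {
    p1 <- curve_params("emax", c(1, 2, 1))
    p2 <- curve_params("exponential", c(level_param, 2.2, 8))
    d <- max_abs_deviation(p1, p2, dose_range = c(0, 4))$d
  } else if (scenario == 2) {
    p1 <- curve_params("emax", c(level_param, 5, 1))
    p2 <- curve_params("emax", c(0, 5, 1))
    d <- abs(level_param)
  } else {
    p1 <- curve_params("exponential", c(level_param, 2.2, 8))
    p2 <- curve_params("exponential", c(0, 2.2, 8))
    d <- abs(level_param)
  }
  list(params1 = p1, params2 = p2, d_true = d)
}

# model specification -> candidate families / weighting per group
spec_setup <- function(specification, scenario) {
  true_fams <- switch(scenario,
    `1` = c("emax", "exponential"),
    `2` = c("emax", "emax"),
    `3` = c("exponential", "exponential")
  )
  switch(specification,
    true      = list(fam = list(true_fams[1], true_fams[2]), weights = "bic"),
    emax_emax = list(fam = list("emax", "emax"), weights = "bic"),
    exp_exp   = list(fam = list("exponential", "exponential"), weights = "bic"),
    swapped   = list(fam = list(
                   setdiff(c("emax", "exponential"), true_fams[1]),
                   setdiff(c("emax", "exponential"), true_fams[2])),
                 weights = "bic"),
    ma_bic    = list(fam = list(c("emax", "exponential"),
                                c("emax", "exponential")), weights = "bic"),
    ma_equal  = list(fam = list(c("emax", "exponential"),
                                c("emax", "exponential")), weights = "equal"),
    stop("unknown specification: ", specification, call. = FALSE)
  )
}

#' Configure one simulation sub-scenario
#'
#' Bundles everything one cell of the simulation study needs: the true
#' curves, the design, the error variances, sample sizes, the margin and
#' level, the model specification under test, and replication counts.
#'
#' @inheritParams scenario_truth
#' @param sigma2 Length-2 error variances (benchmark values
#'   `(0.25, 0.25)`, `(0.25, 0.5)`, `(0.5, 0.5)`).
#' @param n Length-2 per-group totals (benchmark values 10/20/50,
#'   divisible by 5).
#' @param epsilon Equivalence margin; defaults to 1 for scenario 1 and
#'   0.5 for scenarios 2-3.
#' @param alpha Significance level (default 0.05).
#' @param n_sim Simulation repetitions.
#' @param n_boot Bootstrap replicates per test.
#' @param specification One of `"true"`, `"emax_emax"`, `"exp_exp"`,
#'   `"swapped"`, `"ma_bic"`, `"ma_equal"`: which family (or candidate
#'   set) is fitted to each group.  Misspecification variants fit exactly
#'   one family per group; the `ma_*` variants average over
#'   `{emax, exponential}`.
#' @param ci Bound type, `"hybrid"` or `"percentile"`.
#' @param x_levels Design points (default `0:4`).
#' @param n_grid Deviation grid resolution.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario, level_param,
                            sigma2 = c(0.25, 0.25), n = c(50L, 50L),
                            epsilon = NULL, alpha = 0.05,
                            n_sim = 1000L, n_boot = 500L,
                            specification = "ma_bic",
                            ci = "hybrid", x_levels = 0:4,
                            n_grid = 1001L) {
  truth <- scenario_truth(scenario, level_param)
  if (is.null(epsilon)) epsilon <- if (scenario == 1) 1 else 0.5
  setup <- spec_setup(specification, scenario)
  structure(list(
    scenario = scenario, level_param = level_param, truth = truth,
    sigma2 = sigma2, n = as.integer(n), epsilon = epsilon, alpha = alpha,
    n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
    specification = specification, families = setup$fam,
    weights = setup$weights, ci = ci, x_levels = x_levels,
    n_grid = as.integer(n_grid)
  ), class = "scenario_config")
}

#' Run one simulated equivalence test
#'
#' Draws one dataset from the configured true curves and design, runs the
#' configured test, and returns the rejection decision.  Deterministic
#' given `seed`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return Logical: was equivalence concluded?
#' @export
simulate_once <- function(config, seed) {
  dat <- simulate_curve_data(config$truth$params1, config$truth$params2,
                             sigma2 = config$sigma2, n = config$n,
                             x_levels = config$x_levels, seed = seed)
  tst <- equiv_test(dat, families = config$families,
                    weights = config$weights,
                    epsilon = config$epsilon, alpha = config$alpha,
                    n_boot = config$n_boot, ci = config$ci,
                    dose_range = range(config$x_levels),
                    n_grid = config$n_grid,
                    seed = derive_seed(seed, 777L))
  tst$reject
}

#' Empirical rejection rate of a configured test
#'
#' Repeats [simulate_once()] `config$n_sim` times with per-repetition
#' substream seeds derived from the master seed, so the result does not
#' depend on execution order or the number of worker processes.
#'
#' @param config A [scenario_config()].
#' @param seed Integer master seed.
#' @param threads Worker processes (forked; results identical for any
#'   value).
#' @return One-row tibble: scenario descriptors, `rate`, `n_sim`, and the
#'   binomial Monte-Carlo standard error `mc_se`.
#' @export
estimate_rejection_rate <- function(config, seed = 1L, threads = 1L) {
  seeds <- vapply(seq_len(config$n_sim), function(i) derive_seed(seed, i),
                  integer(1))
  run1 <- function(s) simulate_once(config, s)
  rejects <- if (threads > 1L) {
    unlist(parallel::mclapply(seeds, run1, mc.cores = threads,
                              mc.preschedule = TRUE))
  } else {
    vapply(seeds, run1, logical(1))
  }
  rate <- mean(rejects)
  tibble::tibble(
    scenario = config$scenario, specification = config$specification,
    level_param = config$level_param, d_true = config$truth$d_true,
    sigma2_1 = config$sigma2[1], sigma2_2 = config$sigma2[2],
    n1 = config$n[1], n2 = config$n[2],
    epsilon = config$epsilon, alpha = config$alpha, ci = config$ci,
    n_boot = config$n_boot, n_sim = config$n_sim,
    rate = rate, mc_se = sqrt(rate * (1 - rate) / config$n_sim)
  )
}

#' Sweep a grid of simulation sub-scenarios
#'
#' Expands the supplied value grids into sub-scenario configurations and
#' estimates the rejection rate of each, returning a tidy table (one row
#' per cell) ready for plotting or export.
#'
#' @inheritParams scenario_config
#' @param level_params Vector of scenario level parameters.
#' @param sigma2_pairs List of length-2 variance pairs.
#' @param n_pairs List of length-2 sample-size pairs.
#' @param specifications Character vector of specifications to run.
#' @param seed Master seed (each cell derives its own substream).
#' @param threads Worker processes per cell.
#' @return Tibble with one row per cell, see [estimate_rejection_rate()].
#' @export
run_scenario_sweep <- function(scenario, level_params,
                               sigma2_pairs = list(c(0.25, 0.25)),
                               n_pairs = list(c(50L, 50L)),
                               specifications = "ma_bic",
                               epsilon = NULL, alpha = 0.05,
                               n_sim = 1000L, n_boot = 500L, ci = "hybrid",
                               seed = 1L, threads = 1L) {
  grid <- tidyr::expand_grid(
    level_param = level_params,
    sigma2 = sigma2_pairs, n = n_pairs,
    specification = specifications
  )
  purrr::pmap_dfr(grid, function(level_param, sigma2, n, specification) {
    cfg <- scenario_config(scenario, level_param, sigma2 = sigma2, n = n,
                           epsilon = epsilon, alpha = alpha, n_sim = n_sim,
                           n_boot = n_boot, specification = specification,
                           ci = ci)
    cell_seed <- derive_seed(seed,
                             1000L * match(specification, specifications) +
                               round(1e4 * level_param) + sum(n))
    estimate_rejection_rate(cfg, seed = cell_seed, threads = threads)
  })
}
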