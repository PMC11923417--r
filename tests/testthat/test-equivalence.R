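test_that("maximal deviation matches the brute-force grid oracle", {
  cases <- list(
    # scenario-type curves: unique interior maximum
    list(curve_params("emax", c(1, 2, 1)),
         curve_params("exponential", c(0.25, 2.2, 8))),
    list(curve_params("emax", c(1, 2, 1)),
         curve_params("exponential", c(1, 2.2, 8))),
    # shifted curves: flat difference over the whole range
    list(curve_params("emax", c(0.75, 5, 1)),
         curve_params("emax", c(0, 5, 1))),
    # polynomial difference with boundary maximum
    list(curve_params("quadratic", c(0, 1, -0.3)),
         curve_params("linear", c(0.2, 0.1)))
  )
  for (cs in cases) {
    got <- max_abs_deviation(cs[[1]], cs[[2]], dose_range = c(0, 4))
    f1 <- function(x) predict(cs[[1]], x)
    f2 <- function(x) predict(cs[[2]], x)
    want <- oracle_max_dev(f1, f2, 0, 4)
    expect_gte(got$d, want - 1e-12)        # refinement never loses to the grid
    expect_equal(got$d, want, tolerance = 1e-6)
    expect_equal(abs(f1(got$x_at_max) - f2(got$x_at_max)), got$d,
                 tolerance = 1e-9)
  }
  # identical curves
  p <- curve_params("emax", c(1, 2, 1))
  expect_equal(max_abs_deviation(p, p, dose_range = c(0, 4))$d, 0)
})

test_that("shifted-model deviations are exact and flat across the range", {
  dev <- max_abs_deviation(curve_params("emax", c(0.75, 5, 1)),
                           curve_params("emax", c(0, 5, 1)),
                           dose_range = c(0, 4))
  expect_equal(dev$d, 0.75, tolerance = 1e-12)
  xs <- seq(0, 4, length.out = 57)
  expect_equal(abs(eval_curve("exponential", c(0.3, 2.2, 8), xs) -
                     eval_curve("exponential", c(0, 2.2, 8), xs)),
               rep(0.3, 57), tolerance = 1e-12)
})

test_that("scenario-1 true deviations reproduce the printed values", {
  b20 <- c(0.25, 0.5, 0.75, 1, 1.5)
  want <- c(1.5, 1.25, 1, 0.75, 0.5)
  d <- vapply(b20, function(b) {
    max_abs_deviation(curve_params("emax", c(1, 2, 1)),
                      curve_params("exponential", c(b, 2.2, 8)),
                      dose_range = c(0, 4))$d
  }, numeric(1))
  expect_equal(round(d, 2), want)
})

test_that("percentile bound is the floor(n(1-alpha)) order statistic", {
  expect_equal(percentile_upper_bound(sample(1:100), 0.05), 95)
  expect_equal(percentile_upper_bound(rep(3.3, 10), 0.05), 3.3)
  expect_equal(percentile_upper_bound(sample(1:100), 1e-17), 100)
  expect_equal(percentile_upper_bound(sample(1:100), 0.051), 94)
})

test_that("hybrid bound is d_hat plus z times the bootstrap sd", {
  hb <- hybrid_upper_bound(1, c(rep(0.9, 5), rep(1.1, 5)), 0.05)
  expect_equal(hb$se_hat, sd(c(rep(0.9, 5), rep(1.1, 5))))
  expect_equal(hb$u, 1 + hb$se_hat * qnorm(0.95))
  expect_equal(hybrid_upper_bound(1, rep(2, 10), 0.05)$u, 1)  # constant sample
  expect_equal(hybrid_upper_bound(1, c(0.9, 1.1), 0.499999)$u, 1,
               tolerance = 1e-4)                              # z -> 0
})

test_that("decision rule is strict and the relative threshold scales the range", {
  expect_true(decide_equivalence(1, 0.9))
  expect_false(decide_equivalence(1, 1))
  expect_false(decide_equivalence(0.5, 0.51))
  expect_equal(relative_threshold(c(0, 4, 10), 0.2), 2)
  expect_equal(relative_threshold(c(0, 10), 0.25), 2.5)
  expect_error(relative_threshold(rep(1, 5), 0.2), "zero")
  # scaled and absolute decision rules agree
  u <- 1; rng <- 10
  expect_equal(0.2 > u / rng, (0.2 * rng) > u)
})

test_that("bootstrap is reproducible and nonnegative, and test output is consistent", {
  d <- two_group_data(seed = 3, n = c(20, 20))
  t1 <- equiv_test(d, families = c("emax", "exponential"), epsilon = 1,
                   n_boot = 60, seed = 17)
  t2 <- equiv_test(d, families = c("emax", "exponential"), epsilon = 1,
                   n_boot = 60, seed = 17)
  expect_identical(t1$boot_sample, t2$boot_sample)
  expect_length(t1$boot_sample, 60)
  expect_true(all(t1$boot_sample >= 0))
  expect_gte(t1$d_hat, 0)
  expect_identical(t1$reject, t1$epsilon_used > t1$u)
  expect_gte(t1$u, t1$d_hat)   # hybrid dominance at alpha < 0.5
  # percentile variant from the same machinery
  tp <- equiv_test(d, families = c("emax", "exponential"), epsilon = 1,
                   ci = "percentile", n_boot = 60, seed = 17)
  expect_identical(tp$u, percentile_upper_bound(tp$boot_sample, 0.05))
})

test_that("swapping the groups leaves the statistic and decision unchanged", {
  d <- two_group_data(seed = 23, n = c(20, 20))
  swapped <- dplyr::mutate(d, group = ifelse(group == "1", "2", "1"))
  a <- equiv_test(d, families = c("emax", "exponential"), epsilon = 1,
                  n_boot = 80, seed = 5)
  b <- equiv_test(swapped, families = c("emax", "exponential"), epsilon = 1,
                  n_boot = 80, seed = 5)
  expect_equal(a$d_hat, b$d_hat, tolerance = 1e-10)
  expect_equal(a$u, b$u, tolerance = 1e-10)
  expect_identical(a$reject, b$reject)
})

test_that("the decision is monotone in the margin", {
  d <- two_group_data(seed = 29, n = c(20, 20))
  fits_seed <- 11
  eps_grid <- c(0.3, 0.6, 0.9, 1.2, 1.8)
  rejects <- vapply(eps_grid, function(e) {
    equiv_test(d, families = c("emax", "exponential"), epsilon = e,
               n_boot = 50, seed = fits_seed)$reject
  }, logical(1))
  # once the test rejects at some margin it rejects at all larger margins
  expect_true(all(diff(as.integer(rejects)) >= 0))
})

test_that("noise-free identical curves give d near 0 and a rejection", {
  p <- curve_params("emax", c(1, 2, 1))
  d <- dplyr::bind_rows(
    dplyr::mutate(noise_free_data(p, 4), group = "1"),
    dplyr::mutate(noise_free_data(p, 4), group = "2")
  )
  tst <- equiv_test(d, families = list("emax", "emax"), epsilon = 0.5,
                    n_boot = 50, seed = 2)
  expect_lt(tst$d_hat, 1e-6)
  expect_lt(tst$u, 1e-3)      # degenerate bootstrap stays at the fitted curves
  expect_true(tst$reject)
})

test_that("curves far apart relative to the margin are not declared equivalent", {
  d <- simulate_curve_data(curve_params("emax", c(2, 5, 1)),
                           curve_params("emax", c(0, 5, 1)),
                           sigma2 = c(0.01, 0.01), n = c(20, 20), seed = 4)
  tst <- equiv_test(d, families = list("emax", "emax"), epsilon = 0.5,
                    n_boot = 50, seed = 6)
  expect_false(tst$reject)
  expect_gt(tst$d_hat, 1.5)
})

test_that("relative margins resolve against the fitted response range", {
  d <- two_group_data(seed = 37, n = c(20, 20))
  tst <- equiv_test(d, families = c("emax", "exponential"),
                    epsilon_rel = 0.25, n_boot = 50, seed = 7)
  expect_equal(tst$epsilon_used, 0.25 * tst$fitted_range, tolerance = 1e-12)
  expect_equal(tst$u_scaled, tst$u / tst$fitted_range, tolerance = 1e-12)
  # scaled rule epsilon_rel > u_scaled agrees with the absolute rule
  expect_identical(tst$reject, 0.25 > tst$u_scaled)
  expect_error(equiv_test(d, epsilon = 1, epsilon_rel = 0.2), "exactly one")
})

test_that("input validation catches bad groups and margins", {
  d <- two_group_data(seed = 41)
  expect_error(equiv_test(dplyr::filter(d, group == "1"), epsilon = 1),
               "two groups")
  expect_error(equiv_test(d, epsilon = -1), "exactly one|epsilon")
  expect_error(equiv_test(d, epsilon = 1, alpha = 0.7), "alpha")
})
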