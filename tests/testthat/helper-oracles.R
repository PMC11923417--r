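# Independent oracles used across the suite.

# brute-force maximal absolute deviation on a dense grid
oracle_max_dev <- function(f1, f2, lower, upper, n = 1e5 + 1) {
  xs <- seq(lower, upper, length.out = n)
  max(abs(f1(xs) - f2(xs)))
}

# closed-form weighted least squares via the normal equations
oracle_ls <- function(X, y) {
  qr.solve(crossprod(X), crossprod(X, y))
}

# noise-free dataset from a known curve at the standard 5-level design
noise_free_data <- function(params, n_per_level = 4, x_levels = 0:4,
                            group = "1") {
  x <- rep(x_levels, each = n_per_level)
  tibble::tibble(group = group, x = x, y = predict(params, x))
}

# small two-group Gaussian dataset used by several tests
two_group_data <- function(seed = 42, sigma2 = c(0.25, 0.25), n = c(20, 20),
                           p1 = curve_params("emax", c(1, 2, 1)),
                           p2 = curve_params("exponential", c(0.25, 2.2, 8))) {
  simulate_curve_data(p1, p2, sigma2 = sigma2, n = n, seed = seed)
}
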