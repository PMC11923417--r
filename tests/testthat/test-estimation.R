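test_that("log-likelihood, ML variance and information criteria match closed forms", {
  expect_equal(log_likelihood_gaussian(0, 2, 1), -log(2 * pi))
  # at the ML variance the likelihood collapses to -(n/2)(log(2 pi s2) + 1)
  for (n in c(5, 20)) {
    s2 <- 0.37
    expect_equal(log_likelihood_gaussian(n * s2, n, s2),
                 -(n / 2) * (log(2 * pi * s2) + 1))
  }
  expect_error(log_likelihood_gaussian(1, 10, 0), "positive")
  expect_error(log_likelihood_gaussian(1, 0, 1))

  expect_equal(sigma2_ml(4, 4), 1)   # residuals (1,-1,1,-1)
  expect_equal(sigma2_ml(0, 7), 0)
  expect_equal(sigma2_ml(5, 10), 0.5)

  expect_equal(information_criterion(-10, 4, 20, "bic"), 20 + 4 * log(20))
  expect_equal(information_criterion(-10, 4, 20, "aic"), 28)
  # equal dimensions: BIC difference reduces to the likelihood difference
  d_bic <- information_criterion(-8, 4, 57, "bic") -
    information_criterion(-11, 4, 57, "bic")
  expect_equal(d_bic, -2 * (-8 - (-11)))
})

test_that("linear fit interpolates exactly and flags the degenerate variance", {
  d <- tibble::tibble(x = c(0, 1, 2), y = c(1, 3, 5))
  fit <- fit_curve(d, "linear")
  expect_equal(fit$theta, c(1, 2), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  expect_true(fit$degenerate)
})

test_that("quadratic fit matches the normal-equations oracle", {
  set.seed(11)
  x <- rep(0:4, each = 3)
  y <- 1 + 0.5 * x - 0.2 * x^2 + rnorm(length(x), 0, 0.3)
  fit <- fit_curve(tibble::tibble(x = x, y = y), "quadratic")
  X <- cbind(1, x, x^2)
  theta_oracle <- drop(oracle_ls(X, y))
  expect_equal(unname(fit$theta), unname(theta_oracle), tolerance = 1e-8)
  expect_equal(fit$rss, sum((y - X %*% theta_oracle)^2), tolerance = 1e-8)
})

test_that("noise-free nonlinear data are recovered to high accuracy", {
  cases <- list(
    list("emax", c(1, 2, 1)),
    list("exponential", c(0.25, 2.2, 8)),
    list("sigemax", c(0.5, 2, 1.5, 2))
  )
  for (cs in cases) {
    d <- noise_free_data(curve_params(cs[[1]], cs[[2]]), n_per_level = 3)
    fit <- fit_curve(d, cs[[1]], dose_range = c(0, 4))
    expect_equal(unname(fit$theta), cs[[2]], tolerance = 1e-4,
                 info = cs[[1]])
    expect_lt(fit$rss, 1e-8)
  }
})

test_that("multi-start fit is at least as good as a dense nonlinear grid search", {
  set.seed(7)
  d <- two_group_data(seed = 7)
  d1 <- dplyr::filter(d, group == "1")
  for (fam in c("emax", "exponential")) {
    fit <- fit_curve(d1, fam, dose_range = c(0, 4))
    b <- default_bounds(fam, c(0, 4))
    grid <- exp(seq(log(b$lower), log(b$upper), length.out = 2000))
    gfun <- switch(fam,
      emax = function(nu) d1$x / (nu + d1$x),
      exponential = function(nu) exp(d1$x / nu) - 1)
    rss_grid <- min(vapply(grid, function(nu) {
      X <- cbind(1, gfun(nu))
      sum(stats::lm.fit(X, d1$y)$residuals^2)
    }, numeric(1)))
    expect_lte(fit$rss, rss_grid + 1e-8)
  }
})

test_that("OLS equals joint Gaussian ML over (theta, sigma2)", {
  d <- two_group_data(seed = 13, n = c(10, 10))
  d1 <- dplyr::filter(d, group == "1")
  fit <- fit_curve(d1, "emax", dose_range = c(0, 4))
  # profile likelihood at the OLS solution
  ll_ols <- log_likelihood_gaussian(fit$rss, fit$n, fit$sigma2)
  # direct joint maximization via optim from a neutral start
  nll <- function(p) {
    th <- p[1:3]; ls2 <- p[4]
    if (th[3] <= 0) return(1e10)
    mu <- eval_curve("emax", th, d1$x)
    -(-(fit$n / 2) * log(2 * pi * exp(ls2)) -
        sum((d1$y - mu)^2) / (2 * exp(ls2)))
  }
  opt <- stats::optim(c(1, 1, 1, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(-opt$value, ll_ols, tolerance = 1e-4)
  expect_equal(exp(opt$par[4]), fit$sigma2, tolerance = 1e-2)
})

test_that("too few distinct levels triggers an identifiability warning", {
  d <- tibble::tibble(x = rep(c(0, 4), each = 4),
                      y = rnorm(8))
  expect_warning(fit_curve(d, "emax"), "unidentifiable")
})
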