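test_that("candidate families evaluate to their closed-form values", {
  # emax: at x = 0 only the intercept remains; at x = 1 with ED50 = 1 the
  # effect is half of b1
  expect_equal(eval_curve("emax", c(1, 2, 1), 0), 1)
  expect_equal(eval_curve("emax", c(1, 2, 1), 1), 1 + 2 * 1 / (1 + 1))
  # exponential: exp(0) - 1 = 0
  expect_equal(eval_curve("exponential", c(0.25, 2.2, 8), 0), 0.25)
  # sigemax at x = ED50 is half-maximal for any Hill exponent
  for (h in c(0.5, 1, 2, 7)) {
    expect_equal(eval_curve("sigemax", c(0, 1, 2, h), 2), 0.5)
  }
  # linear / quadratic are polynomials
  expect_equal(eval_curve("linear", c(1, 2), c(0, 3)), c(1, 7))
  expect_equal(eval_curve("quadratic", c(1, 2, -1), 2), 1 + 4 - 4)
  # beta: at x = 0 and x = scal the kernel vanishes; the mode of the
  # kernel with d1 = d2 sits at scal/2 where the normalizer makes it b0+b1
  expect_equal(eval_curve("beta", c(1, 3, 2, 2), c(0, 4.8), scal = 4.8),
               c(1, 1))
  expect_equal(eval_curve("beta", c(1, 3, 2, 2), 2.4, scal = 4.8), 4)
})

test_that("vectorized evaluation equals pointwise evaluation", {
  xs <- c(0, 0.7, 1.3, 2.9, 4)
  cases <- list(
    list("linear", c(0.3, -1), NULL),
    list("quadratic", c(0.3, -1, 0.2), NULL),
    list("emax", c(1, 2, 0.7), NULL),
    list("exponential", c(0.2, 1.4, 6), NULL),
    list("sigemax", c(0, 1.7, 1.2, 3), NULL),
    list("beta", c(5, -2, 1.3, 2.1), 4.8)
  )
  for (cs in cases) {
    vec <- eval_curve(cs[[1]], cs[[2]], xs, scal = cs[[3]])
    pt <- vapply(xs, function(x) eval_curve(cs[[1]], cs[[2]], x, scal = cs[[3]]),
                 numeric(1))
    expect_equal(vec, pt, info = cs[[1]])
  }
})

test_that("intercept shifts translate the curve exactly", {
  xs <- seq(0, 4, by = 0.25)
  delta <- 0.75
  for (cs in list(list("emax", c(1, 2, 1), NULL),
                  list("exponential", c(0.25, 2.2, 8), NULL),
                  list("sigemax", c(0, 1.7, 1.2, 3), NULL),
                  list("beta", c(5, -2, 1.3, 2.1), 4.8))) {
    th2 <- cs[[2]]
    th2[1] <- th2[1] + delta
    expect_equal(eval_curve(cs[[1]], th2, xs, scal = cs[[3]]) -
                   eval_curve(cs[[1]], cs[[2]], xs, scal = cs[[3]]),
                 rep(delta, length(xs)), info = cs[[1]])
  }
})

test_that("sigemax with Hill exponent 1 nests emax", {
  xs <- seq(0, 4, by = 0.2)
  expect_equal(eval_curve("sigemax", c(1, 2, 1, 1), xs),
               eval_curve("emax", c(1, 2, 1), xs))
})

test_that("invalid parameters are rejected with the offending coefficient named", {
  expect_error(eval_curve("emax", c(1, 2, -1), 1), "b2")
  expect_error(eval_curve("sigemax", c(1, 2, 1, -1), 1), "b3")
  expect_error(eval_curve("exponential", c(1, 2, 0), 1), "b2")
  expect_error(eval_curve("beta", c(1, 2, 0, 1), 1, scal = 5), "b2")
  expect_error(eval_curve("emax", c(1, 2), 1), "3 coefficients")
  expect_error(eval_curve("gompertz", c(1, 2), 1), "unknown model family")
  # beta is undefined beyond its scale
  expect_error(eval_curve("beta", c(1, 2, 1, 1), 6, scal = 5), "undefined")
})

test_that("default bounds respect parameter domains and the design range", {
  b <- default_bounds("linear", c(0, 4))
  expect_length(b$lower, 0)
  b <- default_bounds("emax", c(0, 4))
  expect_true(b$lower[1] > 0)
  expect_true(b$upper[1] <= 10 * 4)
  b <- default_bounds("exponential", c(0, 4))
  expect_true(b$lower[1] > 0 && b$upper[1] >= 8)  # scenario truth interior
  b <- default_bounds("beta", c(0, 4))
  expect_true(b$scal > 4)  # fixed scale must exceed the largest dose
  expect_equal(b$scal, 1.2 * 4)
  b <- default_bounds("sigemax", c(0, 4))
  expect_true(all(b$lower > 0) && all(b$upper >= b$lower))
})
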