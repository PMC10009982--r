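test_that("density matches closed-form anchors and an independent oracle", {
  expect_equal(sn_pdf(0, sn_params(0, 1, 0)), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # Phi(0) = 1/2 cancels the factor 2 at the location, whatever the shape
  for (l in c(-7, -1, 0, 3, 20))
    expect_equal(sn_pdf(0, sn_params(0, 1, l)), 1 / sqrt(2 * pi),
                 tolerance = 1e-12)
  # frozen from scipy.stats.skewnorm.pdf(1, 5)
  expect_equal(sn_pdf(1, sn_params(0, 1, 5)), 0.48394131031570964,
               tolerance = 1e-12)
  x <- seq(-4, 6, by = 0.5)
  expect_true(all(sn_pdf(x, sn_params(1, 2, 8)) >= 0))
  # density integrates to one
  for (l in c(-5, 0, 2, 20)) {
    total <- integrate(function(t) sn_pdf(t, sn_params(0.5, 1.7, l)),
                       -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("shape zero recovers the normal distribution everywhere", {
  p <- sn_params(1.3, 2.7, 0)
  x <- seq(-8, 10, by = 0.7)
  expect_equal(sn_pdf(x, p), dnorm(x, 1.3, 2.7), tolerance = 1e-10)
  expect_equal(sn_cdf(x, p), pnorm(x, 1.3, 2.7), tolerance = 1e-10)
  pr <- seq(0.05, 0.95, by = 0.05)
  expect_equal(sn_quantile(pr, p), qnorm(pr, 1.3, 2.7), tolerance = 1e-8)
  expect_equal(sn_mean(p), 1.3, tolerance = 1e-12)
  expect_equal(sn_variance(p), 2.7^2, tolerance = 1e-12)
})

test_that("distribution function agrees with Owen's T identity and quadrature", {
  expect_equal(sn_cdf(0, sn_params(0, 1, 0)), 0.5, tolerance = 1e-12)
  # F(0; lambda) = 1/2 - arctan(lambda)/pi
  for (l in c(-3, 1, 5, 12))
    expect_equal(sn_cdf(0, sn_params(0, 1, l)), 0.5 - atan(l) / pi,
                 tolerance = 1e-10)
  expect_equal(sn_cdf(0, sn_params(0, 1, 1)), 0.25, tolerance = 1e-10)
  expect_equal(sn_cdf(40, sn_params(0, 1, 7)), 1, tolerance = 1e-12)
  expect_equal(sn_cdf(-40, sn_params(0, 1, 7)), 0, tolerance = 1e-12)
  for (l in c(-10, -2, 0.5, 5, 20)) {
    p <- sn_params(0, 1, l)
    for (x in c(-2.2, -0.3, 0.8, 2.5))
      expect_equal(sn_cdf(x, p), quad_sn_cdf(x, p), tolerance = 1e-8)
    # non-decreasing up to one-ulp rounding where the CDF saturates
    expect_true(all(diff(sn_cdf(seq(-5, 5, by = 0.1), p)) >=
                      -4 * .Machine$double.eps))
  }
})

test_that("quantile inverts the distribution function", {
  expect_equal(sn_quantile(0.5, sn_params(0, 1, 0)), 0, tolerance = 1e-9)
  expect_equal(sn_quantile(0.25, sn_params(0, 1, 1)), 0, tolerance = 1e-9)
  # frozen from scipy.stats.skewnorm.ppf(0.9, 5, loc=2, scale=3)
  expect_equal(sn_quantile(0.9, sn_params(2, 3, 5)), 6.934560880854418,
               tolerance = 1e-8)
  pr <- seq(0.01, 0.99, by = 0.07)
  for (l in c(-20, -5, 0, 2, 20)) {
    p <- sn_params(-1, 2.5, l)
    expect_equal(sn_cdf(sn_quantile(pr, p), p), pr, tolerance = 1e-8)
  }
  expect_error(sn_quantile(0, sn_params(0, 1, 1)), "strictly inside")
  expect_error(sn_quantile(1.2, sn_params(0, 1, 1)), "strictly inside")
})

test_that("moments match their closed forms, limits and quadrature", {
  expect_equal(sn_mean(sn_params(0, 1, 0)), 0, tolerance = 1e-12)
  # half-normal limit as the shape grows
  expect_equal(sn_mean(sn_params(0, 1, 1e8)), sqrt(2 / pi), tolerance = 1e-7)
  expect_equal(sn_variance(sn_params(0, 1, 1e8)), 1 - 2 / pi,
               tolerance = 1e-7)
  # frozen from scipy.stats.skewnorm.mean(5) / .var(5)
  expect_equal(sn_mean(sn_params(0, 1, 5)), 0.7823901817554269,
               tolerance = 1e-10)
  expect_equal(sn_variance(sn_params(0, 1, 5)), 0.38786560349271015,
               tolerance = 1e-10)
  expect_equal(sn_variance(sn_params(0, 2, 0)), 4, tolerance = 1e-12)
  # the mean carries the sign of the shape
  expect_lt(sn_mean(sn_params(0, 1, -5)), 0)
  for (l in c(-6, -1, 0, 3, 15)) {
    p <- sn_params(0.8, 1.9, l)
    expect_equal(sn_mean(p), quad_sn_mean(p), tolerance = 1e-9)
    expect_equal(sn_variance(p), quad_sn_variance(p), tolerance = 1e-7)
  }
})

test_that("truncated means satisfy anchors, bounds and total expectation", {
  expect_equal(sn_truncated_mean(sn_params(0, 1, 0), upper = 0),
               -sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(sn_truncated_mean(sn_params(0, 1, 0)), 0, tolerance = 1e-12)
  # frozen quadrature value: E[x | x > median] for shape 5
  u5 <- sn_quantile(0.5, sn_params(0, 1, 5))
  expect_equal(sn_truncated_mean(sn_params(0, 1, 5), lower = u5),
               1.2711051667759887, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:20) {
    l <- runif(1, -20, 20)
    p <- sn_params(runif(1, -3, 3), runif(1, 0.2, 4), l)
    u <- sn_quantile(runif(1, 0.05, 0.95), p)
    lo <- sn_truncated_mean(p, upper = u)
    hi <- sn_truncated_mean(p, lower = u)
    tau <- sn_cdf(u, p)
    expect_lt(lo, u); expect_gt(hi, u)
    # law of total expectation
    expect_equal(tau * lo + (1 - tau) * hi, sn_mean(p), tolerance = 1e-9)
    # doubly truncated case against quadrature
    b <- c(sort(sn_quantile(runif(2, 0.02, 0.98), p)))
    if (diff(b) > 1e-3)
      expect_equal(sn_truncated_mean(p, b[1], b[2]),
                   quad_truncated_mean(p, b[1], b[2]), tolerance = 1e-8)
  }
  expect_error(sn_truncated_mean(sn_params(0, 1, 0), lower = 2, upper = 1),
               "strictly less")
  expect_error(sn_truncated_mean(sn_params(0, 1, 20), lower = -60,
                                 upper = -50), "zero probability")
})

test_that("density obeys the reflection symmetry in the shape", {
  x <- seq(-3, 3, by = 0.25)
  for (l in c(0.5, 2, 7, 20)) {
    expect_equal(sn_pdf(x, sn_params(0, 1, l)),
                 sn_pdf(-x, sn_params(0, 1, -l)), tolerance = 1e-13)
    expect_equal(sn_cdf(x, sn_params(0, 1, l)),
                 1 - sn_cdf(-x, sn_params(0, 1, -l)), tolerance = 1e-10)
  }
})

test_that("sampling is reproducible and distributed as the model says", {
  p <- sn_params(0, 1, 10)
  expect_identical(sn_sample(p, 5, seed = 42), sn_sample(p, 5, seed = 42))
  x0 <- sn_sample(sn_params(0, 1, 0), 1e5, seed = 7)
  expect_gt(suppressWarnings(ks.test(x0, pnorm)$p.value), 0.01)
  x10 <- sn_sample(p, 1e5, seed = 8)
  expect_gt(suppressWarnings(
    ks.test(x10, function(q) sn_cdf(q, p))$p.value), 0.01)
  # right skew for positive shape
  expect_gt(mean(((x10 - mean(x10)) / sd(x10))^3), 0)
  expect_equal(mean(x10), sn_mean(p), tolerance = 4 * sd(x10) / sqrt(1e5))
  expect_error(sn_sample(p, 0, seed = 1), "positive count")
  expect_error(sn_sample(p, 5), "seed")
})

test_that("invalid parameters are rejected", {
  expect_error(sn_params(0, 0, 1), "positive")
  expect_error(sn_params(0, -2, 1), "positive")
  expect_error(sn_params(NA, 1, 1), "finite")
  expect_error(sn_pdf(0, c(1, 2)), "triple")
})
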