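test_that("cdf and pdf match their closed forms, limits and each other", {
  # Frechet baseline collapse at beta = 0
  expect_equal(pnexf(1, 1, 0, 1), exp(-1))
  x <- c(0.3, 1, 2.7)
  expect_equal(dnexf(x, 2, 0, 1.5),
               (1.5 / x) * (2 / x)^1.5 * exp(-(2 / x)^1.5), tolerance = 1e-12)

  # cdf equals quadrature of the pdf (adaptive-quadrature oracle)
  expect_equal(pnexf(2, 1, 2, 1.5),
               quad(function(z) dnexf(z, 1, 2, 1.5), 0, 2), tolerance = 1e-8)

  # pdf equals the derivative of the cdf (central finite difference)
  h <- 1e-6
  expect_equal(dnexf(1.3, 1, 2, 1.5),
               (pnexf(1.3 + h, 1, 2, 1.5) - pnexf(1.3 - h, 1, 2, 1.5)) / (2 * h),
               tolerance = 1e-6)

  # normalization
  expect_equal(quad(function(z) dnexf(z, 0.5, 0.5, 0.5), 0, Inf), 1,
               tolerance = 1e-6)

  # extreme arguments give exact limits, never NaN
  expect_identical(pnexf(1e-300, 1, 1, 1), 0)
  expect_equal(pnexf(1e300, 1, 1, 1), 1)
  expect_identical(dnexf(1e-300, 1, 1, 1), 0)
  expect_false(any(is.nan(c(snexf(c(1e-300, 1e300), 1, 1, 1),
                            hnexf(c(1e-300, 1e300), 1, 1, 1)))))
})

test_that("domain violations are rejected", {
  expect_error(dnexf(-1, 1, 1, 1), "positive")
  expect_error(pnexf(0, 1, 1, 1), "positive")
  expect_error(dnexf(1, -1, 1, 1), "alpha")
  expect_error(dnexf(1, 1, -0.5, 1), "beta")
  expect_error(dnexf(1, 1, 1, 0), "lambda")
  expect_error(qnexf(1.2, 1, 1, 1), "strictly within")
  expect_error(qnexf(0, 1, 1, 1), "strictly within")
})

test_that("hazard and reversed hazard satisfy their defining identities", {
  th <- random_thetas(20, seed = 11)
  set.seed(12)
  p <- runif(20, 0.05, 0.95)
  for (i in 1:20) {
    a <- th[i, 1]; b <- th[i, 2]; l <- th[i, 3]
    x <- qnexf(p, a, b, l)      # points in the bulk, where both sides are representable
    # compare on the log scale so extreme-tail densities stay informative
    expect_equal(log(hnexf(x[i], a, b, l)) + log(snexf(x[i], a, b, l)),
                 dnexf(x[i], a, b, l, log = TRUE), tolerance = 1e-10)
    expect_equal(log(rhnexf(x[i], a, b, l)) + log(pnexf(x[i], a, b, l)),
                 dnexf(x[i], a, b, l, log = TRUE), tolerance = 1e-10)
  }
  # closed form (exp(-beta F) factors cancelled) vs pdf/sf
  xg <- seq(0.2, 5, length.out = 50)
  expect_equal(hnexf(xg, 1, 1, 1),
               dnexf(xg, 1, 1, 1) / snexf(xg, 1, 1, 1), tolerance = 1e-10)
  # cumulative hazard is nondecreasing
  expect_true(all(diff(-pnexf(xg, 0.7, 2, 1.3, lower.tail = FALSE, log.p = TRUE))
                  >= 0))
})

test_that("quantile function inverts the cdf via the Lambert W branch", {
  p <- seq(0.001, 0.999, length.out = 201)
  x <- qnexf(p, 1, 1, 1)
  expect_true(all(diff(x) > 0))
  expect_lt(max(abs(pnexf(x, 1, 1, 1) - p)), 1e-8)
  expect_equal(qnexf(pnexf(2, 1, 1, 1), 1, 1, 1), 2, tolerance = 1e-9)

  # bracketing root-finder oracle at the median
  root <- uniroot(function(z) pnexf(z, 1, 1, 1) - 0.5, c(1e-3, 1e3),
                  tol = 1e-12)$root
  expect_equal(qnexf(0.5, 1, 1, 1), root, tolerance = 1e-9)

  # Frechet baseline quantile at beta = 0
  expect_equal(qnexf(p, 2, 0, 1.5), 2 * (-log(p))^(-1 / 1.5), tolerance = 1e-12)

  # large beta stays finite and invertible (log-scale W argument)
  xb <- qnexf(c(0.1, 0.5, 0.9), 100, 120, 0.4)
  expect_true(all(is.finite(xb) & xb > 0))
  expect_equal(pnexf(xb, 100, 120, 0.4), c(0.1, 0.5, 0.9), tolerance = 1e-8)
})

test_that("internal Lambert W solver agrees with pracma on the principal branch", {
  skip_if_not_installed("pracma")
  a <- c(1e-8, 1e-3, 0.5, 1, 5, 50, 700)
  w_pkg <- nexfr:::lambert_w0_log(log(a))
  w_ref <- vapply(a, pracma::lambertWp, numeric(1))
  expect_equal(w_pkg, w_ref, tolerance = 1e-12)
})

test_that("random generation is reproducible inverse-transform sampling", {
  set.seed(42)
  x1 <- rnexf(100, 0.5, 0.5, 0.5)
  set.seed(42)
  x2 <- rnexf(100, 0.5, 0.5, 0.5)
  expect_identical(x1, x2)
  set.seed(42)
  u <- runif(100)
  expect_equal(x1, qnexf(u, 0.5, 0.5, 0.5))

  # empirical CDF close to the model CDF (DKW-style bound at n = 50,000)
  set.seed(7)
  x <- sort(rnexf(50000, 0.5, 0.5, 0.5))
  sup <- max(abs(pnexf(x, 0.5, 0.5, 0.5) - seq_along(x) / 50000))
  expect_lt(sup, 0.012)

  # sample median near the theoretical median
  set.seed(8)
  med <- median(rnexf(1e5, 3, 3, 3))
  expect_equal(med, qnexf(0.5, 3, 3, 3), tolerance = 0.01)
})

test_that("the lambda = 2 inverse-Rayleigh special case follows the general path", {
  x <- c(0.4, 1, 2.5)
  F <- exp(-(1.3 / x)^2)
  expect_equal(pnexf(x, 1.3, 0.8, 2), 1 - (1 - F) * exp(-0.8 * F),
               tolerance = 1e-13)
  f <- (2 / x) * (1.3 / x)^2 * F
  expect_equal(dnexf(x, 1.3, 0.8, 2), f * (1 + 0.8 * (1 - F)) * exp(-0.8 * F),
               tolerance = 1e-13)
})
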