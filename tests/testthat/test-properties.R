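test_that("series expansion reconstructs the exact density", {
  s <- nexf_series(1, 1, 2, K = 40)
  x <- c(0.5, 1, 2)
  expect_lt(max(abs(dnexf_series(x, s) - dnexf(x, 1, 1, 2))), 1e-8)

  # the (m,k) = (0,0) component has zero scale hence contributes nothing
  z <- s[s$m == 0 & s$k == 0, ]
  expect_identical(z$scale, 0)
  expect_equal(nexfr:::dfrechet_(x, 0, 2), numeric(3))

  # coefficient magnitudes follow beta^k/k!
  k3 <- s[s$m == 1 & s$k == 3, "phi"]
  expect_equal(abs(k3), 1 / factorial(3))

  # beta = 0 truncates to the single baseline Frechet component
  s0 <- nexf_series(2, 0, 1.5)
  expect_true(all(s0$k == 0))
  expect_equal(dnexf_series(x, s0), dnexf(x, 2, 0, 1.5), tolerance = 1e-12)
})

test_that("raw moments match quadrature and signal nonexistence", {
  # Frechet mean at beta = 0: alpha * Gamma(1 - 1/lambda)
  expect_equal(nexf_moment(1, 2, 0, 3), 2 * gamma(1 - 1 / 3), tolerance = 1e-10)

  expect_equal(nexf_moment(1, 1, 1, 3),
               quad(function(z) z * dnexf(z, 1, 1, 3), 0, Inf), tolerance = 1e-6)
  expect_equal(nexf_moment(2, 0.8, 2.5, 4),
               quad(function(z) z^2 * dnexf(z, 0.8, 2.5, 4), 0, Inf),
               tolerance = 1e-6)

  expect_warning(m3 <- nexf_moment(3, 1, 1, 2), "does not exist")
  expect_identical(m3, Inf)

  # large beta triggers the quadrature fallback and still agrees
  expect_equal(nexf_moment(1, 1, 40, 3),
               quad(function(z) z * dnexf(z, 1, 40, 3), 0, Inf), tolerance = 1e-6)
})

test_that("central moments and cumulants obey their identities", {
  cm <- nexf_central_moments(2, 1, 1, 5)
  expect_equal(cm$central[1], 0, tolerance = 1e-12)
  mu <- cm$mean
  expect_equal(cm$central[2],
               quad(function(z) (z - mu)^2 * dnexf(z, 1, 1, 5), 0, Inf),
               tolerance = 1e-6)
  expect_equal(cm$cumulants[1], mu)          # k1 = mean
  expect_equal(cm$cumulants[2], cm$central[2])  # k2 = variance
})

test_that("incomplete moments use the upper incomplete gamma and match quadrature", {
  expect_equal(nexf_incomplete_moment(1, 2, 1, 1, 3),
               quad(function(z) z * dnexf(z, 1, 1, 3), 0, 2), tolerance = 1e-6)
  # t -> Inf recovers the full moment
  expect_equal(nexf_incomplete_moment(1, 1e12, 1, 1, 3),
               nexf_moment(1, 1, 1, 3), tolerance = 1e-8)
  # t -> 0 vanishes
  expect_lt(nexf_incomplete_moment(1, 1e-6, 1, 1, 3), 1e-10)
})

test_that("mean residual life and mean inactivity time behave as conditionals", {
  mu <- nexf_moment(1, 1, 1, 3)
  expect_equal(nexf_mrl(1e-9, 1, 1, 3), mu, tolerance = 1e-6)
  # MRL(t) = E[X - t | X > t] by quadrature
  t0 <- 1.5
  cond <- quad(function(z) (z - t0) * dnexf(z, 1, 1, 3), t0, Inf) /
    snexf(t0, 1, 1, 3)
  expect_equal(nexf_mrl(t0, 1, 1, 3), cond, tolerance = 1e-4)
  # MIT lies strictly inside (0, t)
  tg <- c(0.5, 1, 2, 5)
  mit <- nexf_mit(tg, 1, 1, 3)
  expect_true(all(mit > 0 & mit < tg))
  expect_error(nexf_mrl(1, 1, 1, 0.8), "lambda > 1")
})

test_that("Lorenz, Bonferroni and Zenga curves have the inequality-curve shape", {
  p <- seq(0.05, 0.95, by = 0.05)
  L <- nexf_lorenz(p, 1, 1, 3)
  expect_true(all(L <= p + 1e-12))
  expect_true(all(diff(L) > 0))
  expect_true(all(diff(diff(L)) > -1e-10))    # convexity on the grid
  # oracle at the median
  xp <- qnexf(0.5, 1, 1, 3)
  expect_equal(nexf_lorenz(0.5, 1, 1, 3),
               quad(function(z) z * dnexf(z, 1, 1, 3), 0, xp) /
                 nexf_moment(1, 1, 1, 3), tolerance = 1e-6)
  expect_equal(nexf_lorenz(0.9999, 1, 1, 3), 1, tolerance = 1e-2)
  expect_equal(nexf_bonferroni(p, 1, 1, 3), L / p)
  expect_equal(nexf_zenga(p, 1, 1, 3), (L - p) / (p * (1 - L)))
})

test_that("order statistics reduce, mix and match the binomial sum", {
  x <- c(0.6, 1.4)
  expect_equal(dnexf_order(x, 1, 1, 1, 1, 1), dnexf(x, 1, 1, 1))
  expect_equal(pnexf_order(x, 1, 1, 1, 1, 1), pnexf(x, 1, 1, 1))

  # equal-weight mixture over ranks returns the marginal density
  n <- 5
  mix <- Reduce(`+`, lapply(1:n, function(i) dnexf_order(x, i, n, 1, 2, 1.5))) / n
  expect_equal(mix, dnexf(x, 1, 2, 1.5), tolerance = 1e-12)

  # explicit binomial tail sum oracle
  G <- pnexf(x, 1, 1, 1)
  i <- 2; n <- 3
  direct <- sapply(G, function(g) sum(choose(n, i:n) * g^(i:n) * (1 - g)^(n - (i:n))))
  expect_equal(pnexf_order(x, i, n, 1, 1, 1), direct, tolerance = 1e-12)

  # Monte-Carlo frequency oracle for the 2nd of 3 order statistic
  set.seed(13)
  xq <- qnexf(0.6, 1, 1, 1)
  trip <- matrix(rnexf(3 * 2e5, 1, 1, 1), ncol = 3)
  second <- apply(trip, 1, function(z) sort(z)[2])
  expect_equal(mean(second <= xq), pnexf_order(xq, 2, 3, 1, 1, 1),
               tolerance = 0.005)

  expect_error(dnexf_order(1, 4, 3, 1, 1, 1), "integer in 1..n")
})
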