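test_that("censored log-likelihood reduces, factorizes and differentiates", {
  # single complete observation: loglik = log density
  expect_equal(nexf_loglik(c(1, 1, 1), censored_sample(1)),
               dnexf(1, 1, 1, 1, log = TRUE))

  # adding one censored unit multiplies the likelihood by S(T)
  s <- generate_censored_sample(c(0.7, 1.2, 0.9), 30, censor_time = 2, seed = 21)
  s_plus <- censored_sample(as.numeric(s), n_total = attr(s, "n_total") + 1L,
                            censor_time = 2)
  th <- c(0.7, 1.2, 0.9)
  expect_equal(nexf_loglik(th, s_plus) - nexf_loglik(th, s),
               pnexf(2, 0.7, 1.2, 0.9, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-12)

  # analytic gradient against central differences
  g_num <- sapply(1:3, function(i) {
    h <- 1e-6 * max(1, th[i])
    e <- replace(numeric(3), i, h)
    (nexf_loglik(th + e, s) - nexf_loglik(th - e, s)) / (2 * h)
  })
  expect_equal(nexfr:::nexf_loglik_grad(th, s), g_num, tolerance = 1e-6)

  # zero density yields -Inf, never NaN
  expect_identical(nexf_loglik(c(1, -2, 1), s), -Inf)
  expect_identical(nexf_loglik(c(NA, 1, 1), s), -Inf)
})

test_that("spacings telescope and match an independent transcription", {
  # complete sample: the n+1 spacings sum to one for any parameter value
  set.seed(22)
  x <- sort(rnexf(15, 1, 1, 1))
  for (th in list(c(1, 1, 1), c(0.3, 2, 0.7), c(4, 0.2, 2.5))) {
    G <- pnexf(x, th[1], th[2], th[3])
    sp <- c(G[1], diff(G), 1 - G[15])
    expect_equal(sum(sp), 1, tolerance = 1e-12)
  }

  # package objective equals a direct transcription on random inputs near the
  # generating value (where no spacing is small enough for the naive oracle
  # formula to lose digits to cancellation)
  set.seed(23)
  for (i in 1:10) {
    th <- 0.5 * exp(runif(3, -0.3, 0.3))
    s <- generate_censored_sample(c(0.5, 0.5, 0.5), 25,
                                  censor_time = if (i %% 2) Inf else 3)
    if (length(s) < 2) next
    expect_equal(nexf_mps(th, s),
                 mps_transcription(th, as.numeric(s), attr(s, "n_total"),
                                   attr(s, "censor_time")),
                 tolerance = 1e-10)
  }

  # at the truth, spacings behave like normalised Exp(1) gaps, so the mean
  # log-spacing approaches -log(n + 1) + psi(1) (Euler's constant correction)
  set.seed(24)
  n <- 4000
  x <- sort(rnexf(n, 1, 1, 2))
  G <- pnexf(x, 1, 1, 2)
  expect_equal(mean(log(c(G[1], diff(G), 1 - G[n]))),
               -log(n + 1) + digamma(1), tolerance = 0.02)
})

test_that("maximum likelihood recovers parameters on a large sample", {
  set.seed(25)
  s <- generate_censored_sample(c(0.5, 0.5, 0.5), 2000)
  fit <- suppressWarnings(nexf_fit(s))
  expect_true(fit$converged)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - c(0.5, 0.5, 0.5)) < 4 * se))
  # the gradient vanishes at the reported optimum
  g <- nexfr:::nexf_loglik_grad(coef(fit), s)
  expect_lt(max(abs(g) / max(1, abs(fit$objective))), 1e-4)
})

test_that("fits depend only on the order statistics", {
  set.seed(26)
  x <- rnexf(80, 1, 1, 1.5)
  f1 <- suppressWarnings(nexf_fit(x, n_starts = 2))
  f2 <- suppressWarnings(nexf_fit(sample(x), n_starts = 2))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
})

test_that("both estimators are consistent: error shrinks from n = 50 to n = 200", {
  R <- 60
  sqerr <- function(n, method) {
    out <- numeric(R)
    for (r in seq_len(R)) {
      s <- generate_censored_sample(c(0.5, 0.5, 0.5), n, seed = 2600 + r)
      f <- suppressWarnings(nexf_fit(s, method = method, n_starts = 1,
                                     hessian = FALSE))
      out[r] <- (coef(f)[3] - 0.5)^2
    }
    mean(out)
  }
  expect_lt(sqerr(200, "mle"), sqerr(50, "mle"))
  expect_lt(sqerr(200, "mps"), sqerr(50, "mps"))
})

test_that("a quasi-Newton optimum is a Newton-Raphson fixed point", {
  set.seed(27)
  s <- generate_censored_sample(c(1, 0.5, 1.5), 400)
  fit <- suppressWarnings(nexf_fit(s, n_starts = 2))
  th <- coef(fit)
  H <- -observed_information(th, s)
  g <- nexfr:::nexf_loglik_grad(th, s)
  step <- solve(H, g)
  expect_lt(max(abs(step)), 1e-4)    # one Newton step does not move the estimate
})

test_that("tied failure times are jittered with a warning", {
  x <- c(0.5, 1, 1, 2)
  expect_warning(v <- nexf_mps(c(1, 1, 1), censored_sample(x)), "jitter")
  expect_true(is.finite(v))
})

test_that("fit objects expose the standard modelling methods", {
  s <- generate_censored_sample(c(0.5, 0.5, 0.5), 120, censor_time = 3, seed = 28)
  fit <- suppressWarnings(nexf_fit(s))
  expect_s3_class(fit, "nexf_fit")
  expect_named(coef(fit), c("alpha", "beta", "lambda"))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_equal(as.numeric(logLik(fit)), nexf_loglik(coef(fit), s),
               tolerance = 1e-8)
  expect_output(print(fit), "NEXF MLE fit")
  expect_output(print(summary(fit)), "asymptotic intervals")
  # Cox-Snell residuals are nonnegative (0 only by survival underflow to 1)
  rs <- residuals(fit)
  expect_true(all(rs >= 0) && any(rs > 0))
  # predict round trip
  expect_equal(predict(fit, 0.5, type = "quantile"),
               unname(qnexf(0.5, coef(fit)[1], coef(fit)[2], coef(fit)[3])))
  # simulate honours the fitted censoring scheme
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "censored_sample")
  expect_equal(attr(sim[[1]], "censor_time"), 3)
})
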