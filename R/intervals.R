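#' Observed Fisher information and asymptotic confidence intervals
#'
#' `observed_information` returns the negative Hessian of the Type-I
#' censored NEXF log-likelihood at `theta`, computed by central finite
#' differences (step `h * max(1, |theta_i|)`) with optional one-level
#' Richardson extrapolation, and symmetrised.  Its inverse estimates the
#' sampling covariance of the estimator; `asymptotic_ci` turns that into
#' per-parameter normal-theory intervals
#' \eqn{\hat\vartheta \pm z_{1-\gamma/2}\sqrt{V_{\hat\vartheta}}}.
#' The information is always evaluated on the log-likelihood surface, also
#' when the point estimate comes from maximum product of spacings.
#'
#' @param theta parameter vector `c(alpha, beta, lambda)` at an interior
#'   optimum, or for `asymptotic_ci` an [nexf_fit] object.
#' @param sample a [censored_sample].
#' @param fn objective whose curvature is measured (default [nexf_loglik];
#'   any `function(theta, sample)` may be supplied).
#' @param h base relative step size.
#' @param richardson logical; one Richardson refinement (default TRUE).
#' @param level confidence level.
#' @return `observed_information`: a symmetric 3x3 matrix.
#'   `asymptotic_ci`: a data frame with columns `estimate`, `low`, `high`,
#'   `length` (one row per parameter), or an error if the information matrix
#'   is singular or indefinite (interval suppressed rather than bogus).
#' @examples
#' s <- generate_censored_sample(c(0.5, 0.5, 0.5), 300, seed = 2)
#' fit <- nexf_fit(s)
#' asymptotic_ci(fit)
#' @export
observed_information <- function(theta, sample, fn = nexf_loglik,
                                 h = 1e-4, richardson = TRUE) {
  ## h ~ eps^(1/4): below this, rounding noise in the second differences
  ## dominates the truncation error they are meant to remove
  f <- function(th) fn(th, sample)
  H1 <- neg_hessian_fd(f, theta, h)
  if (richardson) {
    H2 <- neg_hessian_fd(f, theta, 2 * h)
    H1 <- (4 * H1 - H2) / 3
  }
  (H1 + t(H1)) / 2
}

## negative Hessian by plain central differences
neg_hessian_fd <- function(f, x, h) {
  p <- length(x)
  hh <- h * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, hh[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, hh[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  -H
}

#' @rdname observed_information
#' @export
asymptotic_ci <- function(theta, sample = NULL, level = 0.95, ...) {
  safe_inv <- function(I) tryCatch(solve(I), error = function(e) NULL)
  if (inherits(theta, "nexf_fit")) {
    fit <- theta
    est <- coef(fit)
    V <- fit$vcov
    if (is.null(V)) V <- safe_inv(observed_information(est, fit$sample, ...))
  } else {
    est <- theta
    V <- safe_inv(observed_information(est, sample, ...))
  }
  v <- if (is.null(V)) NA_real_ else diag(V)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("information matrix indefinite or singular; intervals suppressed. ",
         "Check convergence or refit with another start.", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  data.frame(estimate = est, low = est - z * se, high = est + z * se,
             length = 2 * z * se,
             row.names = c("alpha", "beta", "lambda"))
}
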