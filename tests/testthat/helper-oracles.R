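# shared oracle helpers: quadrature against the closed forms, and a
# deterministic generator of random parameter points

quad <- function(f, lower, upper, ...) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10, ...)$value
}

# random parameter triples (alpha, beta, lambda) in (0.1, 5)^3 under a fixed
# seed; no dimnames, so scalar subsets stay unnamed in oracle expressions
random_thetas <- function(n, seed = 20260927, lo = 0.1, hi = 5) {
  set.seed(seed)
  matrix(stats::runif(3 * n, lo, hi), ncol = 3)
}

# direct transcription of the censored log-product-of-spacings, written
# independently of the package internals (plain CDF differences)
mps_transcription <- function(theta, x, n, Tc) {
  G <- function(z) {
    F <- exp(-(theta[1] / z)^theta[3])
    1 - (1 - F) * exp(-theta[2] * F)
  }
  m <- length(x)
  val <- log(G(x[1])) + log(1 - G(x[m]))
  if (m > 1) val <- val + sum(log(G(x[-1]) - G(x[-m])))
  if (n > m) val <- val + (n - m) * log(1 - G(Tc))
  val
}
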