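# nexfr

Survival analysts modelling remission or failure times with *non-monotone*
hazards — decreasing or upside-down shapes that the exponential and plain
Fréchet families cannot express — and life tests terminated at a fixed time
(Type-I censoring) need a parametric model plus an inference toolkit that
respects the censoring. `nexfr` provides both for the **New Exponential-X
Fréchet (NEXF)** lifetime distribution.

## The model

Pushing a Fréchet baseline F(x) = exp{−(α/x)^λ} through the exponential-X
family transform gives

    G(x) = 1 − (1 − F(x)) e^{−β F(x)},
    g(x) = f(x) (1 + β(1 − F(x))) e^{−β F(x)},      x > 0,

with Fréchet scale α > 0, family shape β > 0 and tail shape λ > 0
(moments of order r exist only for r < λ; β → 0 recovers the Fréchet
baseline, λ = 2 the inverse-Rayleigh case). The quantile function is
closed-form via the principal Lambert-W branch, so random generation is
pure inverse transform.

For a Type-I censored sample (m failures x₁ ≤ … ≤ x_m observed before the
fixed termination time T, out of n units) the package offers

* **distribution functions and properties** — `dnexf/pnexf/qnexf/rnexf`,
  hazards, series expansion, (incomplete) moments, mean residual life,
  Lorenz/Bonferroni/Zenga curves, order statistics;
* **frequentist fitting** — `nexf_fit()` maximizes the censored
  log-likelihood ℓ(Θ) = Σ log g(xᵢ) + (n−m) log S(T) or the censored
  log-product-of-spacings, returning a classed fit with `print`, `summary`,
  `coef`, `vcov`, `confint` (observed-information intervals), `predict`,
  `residuals` (Cox–Snell), `simulate` and `plot` methods;
* **Bayesian fitting** — `nexf_bayes()`: gamma priors, random-walk
  Metropolis–Hastings on log-parameters, posterior-mean estimates and
  `hpd_interval()` credible intervals;
* **a Monte-Carlo harness** — `nexf_sim_cell()` / `nexf_sim_table()` for
  bias / MSE / interval-length studies;
* **censored model selection** — `compare_models()` with AIC/CAIC/BIC/HQIC
  and a modified Kolmogorov–Smirnov test (`censored_ks()`) whose p-value is
  calibrated by parametric bootstrap.

## Worked example

The packaged fixture `leukemia_synthetic.csv` is a *synthetic* stand-in for
a remission-time trial: 40 patients, trial stopped at day 205, only the 20
failures before day 205 recorded (the generating parameters are in the
`.meta` sidecar).

```r
library(nexfr)
p <- system.file("extdata", "leukemia_synthetic.csv", package = "nexfr")
s <- censored_sample(read_times(p), n_total = 40, censor_time = 205)

fit <- nexf_fit(s)                 # censored MLE
fit
#> NEXF MLE fit (Type-I censored: m = 20 of n = 40, T = 205)
#>     alpha      beta    lambda
#> 1306.2396   12.6004    0.5891
#> log-likelihood: -129.6517   objective: -129.6517   converged: TRUE

compare_models(s, n_boot = 200, seed = 7)
#>         model k    loglik      AIC     CAIC      BIC     HQIC     KS p_value
#> 1        nexf 3 -129.6517 265.3033 265.9700 270.3700 267.1353 0.0596  0.6685
#> 2 exponential 1 -136.2990 274.5980 274.7032 276.2868 275.2086 0.1683  0.0000
#> 3     frechet 2 -129.9869 263.9737 264.2981 267.3515 265.1950 0.0826  0.2400
#> 4    frechet3 3 -129.7490 265.4979 266.1646 270.5645 267.3298 0.0614  0.6989
#> best by AIC: frechet
```

Reading the comparison: the exponential is firmly rejected (its modified-KS
bootstrap p-value is 0.000 — a constant hazard cannot track these data),
while NEXF fits well (p = 0.67, the smallest KS distance of the four). On
this particular synthetic draw the two-parameter Fréchet edges out NEXF on
AIC by 1.3 points — with n = 40 and heavy censoring the extra shape
parameter is not always worth its penalty, which is exactly what the
criteria are for.

The Bayesian route on the same data:

```r
post <- nexf_bayes(s, n_iter = 4000, burn_in = 1000, seed = 11)
coef(post)                          # posterior means (squared-error loss)
#>     alpha      beta    lambda
#> 1420.5114   12.4868    0.5987
hpd_interval(post$draws[, "lambda"])
#>       low      high
#> 0.4336728 0.8154238
```

A small simulation cell (bias / MSE / mean 95% CI length per parameter and
method):

```r
nexf_sim_cell(c(0.5, 0.5, 0.5), n = 50, censor_time = 1.5,
              n_reps = 200, seed = 1)
```

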