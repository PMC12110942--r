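## Shared fixtures and oracles for the test suite.

## mid-range dependence parameters per family (Kendall tau ~ 0.4-0.5)
mid_theta <- c(clayton = 2, frank = 5, gumbel = 2, normal = 0.6)

copula_families <- c("clayton", "frank", "gumbel", "normal")
margin_families <- c("exponential", "weibull", "gompertz")

## finite-difference oracles on the copula CDF
fd_density <- function(family, u, v, theta, h = 1e-5) {
  (copula_cdf(family, u + h, v + h, theta) -
     copula_cdf(family, u + h, v - h, theta) -
     copula_cdf(family, u - h, v + h, theta) +
     copula_cdf(family, u - h, v - h, theta)) / (4 * h * h)
}

fd_h <- function(family, u, v, theta, wrt = "first", h = 1e-6) {
  if (wrt == "first")
    (copula_cdf(family, u + h, v, theta) -
       copula_cdf(family, u - h, v, theta)) / (2 * h)
  else
    (copula_cdf(family, u, v + h, theta) -
       copula_cdf(family, u, v - h, theta)) / (2 * h)
}

## small dataset for fast fitting tests
small_design <- function(copula = "clayton", n = 400, ...) {
  sccr_design(copula = copula, n = n, ...)
}
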