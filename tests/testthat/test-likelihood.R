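test_that("parameter packing is a lossless round trip for all 12 models", {
  for (cop in copula_families) {
    for (m1 in margin_families) {
      for (m2 in margin_families[1:2]) {
        spec <- sccr_spec(cop, m1, m2, c("Z1", "Z2"))
        a1 <- if (spec$has_shape1) 2.6 else NULL
        a2 <- if (spec$has_shape2) 2.99 else NULL
        phi <- pack_params(a1, a2, c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), spec)
        expect_length(phi, spec$n_par)
        up <- unpack_params(phi, spec)
        expect_equal(up$alpha1, a1)
        expect_equal(up$alpha2, a2)
        expect_equal(up$beta1, c(1, 2, 3))
        expect_equal(up$beta2, c(4, 5, 6))
        expect_equal(up$b, c(7, 8, 9))
      }
    }
  }
  ## layout sizes: 3(p+1) plus one slot per shape parameter
  expect_equal(sccr_spec("clayton", "exponential", "exponential",
                         c("a", "b"))$n_par, 9)
  expect_equal(sccr_spec("clayton", "weibull", "weibull",
                         c("a", "b"))$n_par, 11)
  expect_error(pack_params(NULL, NULL, c(1, 2), c(3, 4), c(5, 6),
                           sccr_spec("clayton", covariates = c("x", "y"))),
               "length")
})

test_that("single-record likelihood branches equal their closed forms", {
  spec <- sccr_spec("clayton", "exponential", "exponential", c("Z1", "Z2"))
  phi <- pack_params(NULL, NULL, c(0.4, 0.2, -0.1), c(-0.2, 0.5, 0.3),
                     c(0.7, 0.1, -0.5), spec)
  z <- c(0.3, 1)
  lam1 <- rate_param(phi[1:3], z); lam2 <- rate_param(phi[4:6], z)
  th <- link_theta("clayton", phi[7:9], z)
  x <- 0.4; y <- 0.9
  u <- margin_survival("exponential", x, lam1)
  v <- margin_survival("exponential", y, lam2)
  rec <- function(d1, d2, x., y.)
    data.frame(time1 = x., status1 = d1, time2 = y., status2 = d2,
               Z1 = z[1], Z2 = z[2])
  ## both events observed: copula density times both marginal densities
  expect_equal(sc_loglik(phi, rec(1, 1, x, y), spec),
               log(copula_density("clayton", u, v, th)) +
                 log(margin_density("exponential", x, lam1)) +
                 log(margin_density("exponential", y, lam2)))
  ## non-terminal observed, terminal censored: h-function branch
  expect_equal(sc_loglik(phi, rec(1, 0, x, y), spec),
               log(h_function("clayton", u, v, th, "first")) +
                 log(margin_density("exponential", x, lam1)))
  ## terminal first (x = y): h wrt the second argument
  uy <- margin_survival("exponential", y, lam1)
  expect_equal(sc_loglik(phi, rec(0, 1, y, y), spec),
               log(h_function("clayton", uy, v, th, "second")) +
                 log(margin_density("exponential", y, lam2)))
  ## both censored: the joint survival copula
  expect_equal(sc_loglik(phi, rec(0, 0, y, y), spec),
               log(copula_cdf("clayton", uy, v, th)))
})

test_that("likelihood factorizes into the margins at independence", {
  des <- small_design(n = 500)
  dat <- rsemicompeting(des, seed = 3)
  for (setup in list(
    list(cop = "clayton", b0 = -20),
    list(cop = "frank", b0 = 0),        # identity link through zero
    list(cop = "normal", b0 = 0))) {
    spec <- sccr_spec(setup$cop, "exponential", "exponential",
                      c("Z1", "Z2"))
    phi <- pack_params(NULL, NULL, des$beta_nt, des$beta_t,
                       c(setup$b0, 0, 0), spec)
    joint <- sc_loglik(phi, dat, spec)
    fac <- margin_censored_loglik("exponential", dat$time1, dat$status1,
                                  dat[c("Z1", "Z2")], des$beta_nt) +
      margin_censored_loglik("exponential", dat$time2, dat$status2,
                             dat[c("Z1", "Z2")], des$beta_t)
    expect_equal(joint, fac, tolerance = 1e-4)
  }
})

test_that("likelihood is finite on its own support and peaks near the truth", {
  set.seed(14)
  for (cop in copula_families) {
    des <- small_design(copula = cop, n = 300)
    dat <- rsemicompeting(des, seed = 5)
    spec <- des$spec
    ll0 <- sc_loglik(des$truth, dat, spec)
    expect_true(is.finite(ll0))
    ## concentration sanity: truth beats most random unit perturbations
    worse <- vapply(1:50, function(i) {
      d <- rnorm(spec$n_par); d <- d / sqrt(sum(d * d))
      sc_loglik(des$truth + d, dat, spec) < ll0
    }, logical(1))
    expect_gte(mean(worse), 0.95)
  }
})

test_that("singly-censored branches match numeric differentiation of the joint survival", {
  spec <- sccr_spec("gumbel", "exponential", "exponential", c("Z1", "Z2"))
  phi <- pack_params(NULL, NULL, c(0.4, 0.2, -0.1), c(-0.2, 0.5, 0.3),
                     c(0.2, 0.1, -0.3), spec)
  z <- c(0.6, 0)
  lam1 <- rate_param(phi[1:3], z); lam2 <- rate_param(phi[4:6], z)
  th <- link_theta("gumbel", phi[7:9], z)
  S <- function(t1, t2) copula_cdf("gumbel",
                                   margin_survival("exponential", t1, lam1),
                                   margin_survival("exponential", t2, lam2),
                                   th)
  x <- 0.5; y <- 1.1; h <- 1e-6
  dat10 <- data.frame(time1 = x, status1 = 1, time2 = y, status2 = 0,
                      Z1 = z[1], Z2 = z[2])
  ## (1,0): contribution is -dS/dt1 at (x, y)
  expect_equal(exp(sc_loglik(phi, dat10, spec)),
               -(S(x + h, y) - S(x - h, y)) / (2 * h), tolerance = 1e-4)
  dat01 <- data.frame(time1 = y, status1 = 0, time2 = y, status2 = 1,
                      Z1 = z[1], Z2 = z[2])
  expect_equal(exp(sc_loglik(phi, dat01, spec)),
               -(S(y, y + h) - S(y, y - h)) / (2 * h), tolerance = 1e-4)
})

test_that("inadmissible parameters give the sentinel; structural errors raise", {
  spec <- sccr_spec("clayton", "weibull", "exponential", c("Z1", "Z2"))
  dat <- rsemicompeting(small_design(n = 50), seed = 1)
  phi <- pack_params(2.6, NULL, c(1, 0, 0), c(1, 0, 0), c(0, 0, 0), spec)
  expect_true(is.finite(sc_loglik(phi, dat, spec)))
  bad <- phi; bad[1] <- -1  # negative shape
  expect_equal(sc_loglik(bad, dat, spec), -.Machine$double.xmax)
  expect_error(sc_loglik(phi[-1], dat, spec), "length")
  expect_error(sc_loglik(phi, dat[0, ], spec), "empty")
})

test_that("AIC arithmetic and invariances", {
  expect_equal(aic(0, 9), 18)
  expect_equal(aic(-150.67, 9), 319.34)
  l1 <- -200; l2 <- -190; const <- 12.3
  expect_equal(aic(l1, 9) - aic(l2, 9),
               aic(l1 + const, 9) - aic(l2 + const, 9))
  expect_error(aic(0, 0), "k")
})
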