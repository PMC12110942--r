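test_that("copula CDF closed forms match hand values", {
  expect_equal(copula_cdf("clayton", 0.5, 1.0, 2), 0.5)
  expect_equal(copula_cdf("clayton", 0.5, 0.5, 1), 1 / 3)
  expect_equal(copula_cdf("gumbel", exp(-1), exp(-1), 2), exp(-sqrt(2)))
  ## Frank at near-zero theta degenerates to independence
  expect_equal(copula_cdf("frank", 0.3, 0.7, 1e-9), 0.3 * 0.7,
               tolerance = 1e-6)
})

test_that("copula boundary conditions hold across families", {
  set.seed(11)
  for (fam in copula_families) {
    u <- runif(100)
    th <- mid_theta[[fam]]
    expect_equal(copula_cdf(fam, u, rep(1, 100), th), u, tolerance = 1e-12)
    expect_equal(copula_cdf(fam, rep(1, 100), u, th), u, tolerance = 1e-12)
    expect_equal(copula_cdf(fam, u, rep(0, 100), th), rep(0, 100))
    expect_equal(copula_cdf(fam, rep(0, 100), u, th), rep(0, 100))
  }
})

test_that("inadmissible dependence parameters raise domain errors", {
  expect_error(copula_cdf("clayton", 0.5, 0.5, -1), "\\(0, Inf\\)")
  expect_error(copula_cdf("frank", 0.5, 0.5, 0), "frank")
  expect_error(copula_cdf("gumbel", 0.5, 0.5, 0.8), "\\[1, Inf\\)")
  expect_error(copula_cdf("normal", 0.5, 0.5, 1.2), "\\[-1, 1\\]")
  expect_error(copula_cdf("clayton", NaN, 0.5, 1), "NaN")
  expect_error(copula_density("clayton", 0, 0.5, 1), "open")
})

test_that("copula density matches the finite-difference oracle on a grid", {
  grid <- seq(0.1, 0.9, length.out = 10)
  thetas <- list(clayton = c(0.5, 2, 5), frank = c(-4, 2, 8),
                 gumbel = c(1.2, 2, 4), normal = c(-0.5, 0.3, 0.8))
  for (fam in copula_families) {
    for (th in thetas[[fam]]) {
      for (u in grid) {
        d <- copula_density(fam, u, grid, th)
        fd <- fd_density(fam, u, grid, th)
        expect_equal(d, fd, tolerance = 1e-5)
        expect_true(all(d >= 0))
      }
    }
  }
})

test_that("density at independence parameters is 1", {
  expect_equal(copula_density("normal", 0.37, 0.81, 0), 1)
  expect_equal(copula_density("clayton", 0.4, 0.6, 1e-9), 1,
               tolerance = 1e-6)
  expect_equal(copula_density("frank", 0.4, 0.6, 1e-10), 1)
})

test_that("copula density integrates to 1 over the unit square", {
  gl <- sccr:::.gauss_legendre_01(64)
  for (fam in copula_families) {
    th <- mid_theta[[fam]]
    W <- outer(gl$weights, gl$weights)
    D <- outer(gl$nodes, gl$nodes,
               function(u, v) copula_density(fam, u, v, th))
    expect_equal(sum(W * D), 1, tolerance = 1e-3)
  }
})

test_that("h-functions match finite differences and boundary identities", {
  expect_equal(h_function("clayton", 0.5, 1.0, 3, "first"), 1)
  expect_equal(h_function("normal", 0.4, 0.7, 0, "first"), 0.7)
  for (fam in copula_families) {
    th <- mid_theta[[fam]]
    for (side in c("first", "second")) {
      hv <- h_function(fam, 0.25, 0.6, th, side)
      expect_equal(hv, fd_h(fam, 0.25, 0.6, th, side), tolerance = 1e-6)
      expect_gte(hv, 0); expect_lte(hv, 1)
    }
    ## monotone non-decreasing in the non-conditioned argument
    vs <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(diff(h_function(fam, 0.35, vs, th, "first")) >= 0))
  }
})

test_that("inverse_h inverts the h-function for every family", {
  set.seed(22)
  for (fam in copula_families) {
    th <- mid_theta[[fam]]
    u <- runif(50, 0.02, 0.98); v <- runif(50, 0.02, 0.98)
    w <- h_function(fam, u, v, th, "first")
    expect_equal(inverse_h(fam, w, u, th), v, tolerance = 1e-8)
  }
  expect_equal(inverse_h("normal", 0.42, 0.9, 0), 0.42)
})

test_that("Gumbel inverse_h agrees with an independent bisection oracle", {
  bisect <- function(w, u, th) {
    lo <- 1e-12; hi <- 1 - 1e-12
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (h_function("gumbel", u, mid, th, "first") < w) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }
  for (w in c(0.1, 0.5, 0.9)) {
    expect_equal(inverse_h("gumbel", w, 0.5, 2), bisect(w, 0.5, 2),
                 tolerance = 1e-8)
  }
})

test_that("link functions map coefficients into each admissible range", {
  expect_equal(link_theta("clayton", c(0, 0, 0), c(0.3, 1)), 1)
  expect_equal(link_theta("gumbel", c(0, 0, 0), c(0.3, 1)), 2)
  ## the reference design truth: theta at z = 0 is exp(b0)
  expect_equal(link_theta("clayton", c(1.260, -0.037, -1.200), c(0, 0)),
               exp(1.260), tolerance = 1e-4)
  expect_error(link_theta("clayton", c(0, 0), c(0.3, 1)), "length")
  set.seed(33)
  for (fam in copula_families) {
    b <- rnorm(3, 0, 2)
    z <- cbind(runif(200), rbinom(200, 1, 0.5))
    th <- link_theta(fam, b, z)
    expect_true(all(.subset2(list(
      clayton = th > 0, frank = is.finite(th),
      gumbel = th >= 1, normal = th >= -1 & th <= 1), fam)))
  }
})

test_that("Kendall's tau closed forms and Frank quadrature are correct", {
  expect_equal(kendall_tau("clayton", 2), 0.5)
  expect_equal(kendall_tau("gumbel", 1), 0)
  expect_equal(kendall_tau("normal", sin(pi * 0.3 / 2)), 0.3)
  ## Frank via Debye quadrature vs Monte-Carlo concordance
  set.seed(44)
  n <- 1e5
  u <- runif(n); v <- inverse_h("frank", runif(n), u, 5)
  i <- seq_len(n / 2) * 2
  conc <- sign((u[i] - u[i - 1]) * (v[i] - v[i - 1]))
  expect_equal(kendall_tau("frank", 5), mean(conc), tolerance = 0.01)
  expect_equal(kendall_tau("frank", -5), -kendall_tau("frank", 5))
})

test_that("conditional-inversion sampling reproduces closed-form tau", {
  set.seed(55)
  n <- 20000
  for (fam in copula_families) {
    for (tau in c(0.2, 0.5, 0.7)) {
      th <- switch(fam,
        clayton = 2 * tau / (1 - tau),
        gumbel  = 1 / (1 - tau),
        normal  = sin(pi * tau / 2),
        frank   = uniroot(function(t) kendall_tau("frank", t) - tau,
                          c(0.1, 100))$root)
      u <- runif(n)
      v <- inverse_h(fam, runif(n), u, th)
      ## fast unbiased tau estimate from random disjoint pairs
      i <- seq_len(n / 2) * 2
      conc <- sign((u[i] - u[i - 1]) * (v[i] - v[i - 1]))
      se <- sd(conc) / sqrt(length(conc))
      expect_lt(abs(mean(conc) - tau), 3 * se + 1e-3)
    }
  }
})

test_that("vectorized bivariate normal CDF matches mvtnorm", {
  skip_if_not_installed("mvtnorm")
  set.seed(66)
  for (r in c(-0.995, -0.6, 0, 0.3, 0.9, 0.995)) {
    x <- rnorm(20); y <- rnorm(20)
    ref <- vapply(seq_along(x), function(i)
      mvtnorm::pmvnorm(upper = c(x[i], y[i]),
                       corr = matrix(c(1, r, r, 1), 2))[1], numeric(1))
    ## absolute comparison: pmvnorm's own accuracy is ~1e-8 in the tails
    expect_lt(max(abs(sccr:::pbvnorm(x, y, r) - ref)), 1e-7)
  }
})
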