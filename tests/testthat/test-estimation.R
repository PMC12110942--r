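test_that("grid search enumerates the Cartesian product and finds the max", {
  expect_equal(grid_search_init(function(p) -(p[1] - 1)^2, -3, 3, 7), 1)
  calls <- 0
  obj <- function(p) { calls <<- calls + 1; -sum(p^2) }
  res <- grid_search_init(obj, c(-3, -3), c(3, 3), 3)
  expect_equal(calls, 9)  # n_grid^dim evaluations
  expect_equal(res, c(0, 0))
  ## matches exhaustive enumeration on random quadratics
  set.seed(21)
  for (i in 1:100) {
    ctr <- runif(2, -2, 2)
    f <- function(p) -sum((p - ctr)^2)
    axes <- list(seq(-3, 3, length.out = 4), seq(-2, 2, length.out = 4))
    pts <- expand.grid(axes[[1]], axes[[2]])
    brute <- unname(unlist(pts[which.max(apply(pts, 1, f)), ]))
    expect_equal(grid_search_init(f, c(-3, -2), c(3, 2), 4), brute)
  }
  expect_error(grid_search_init(function(p) -Inf, -1, 1, 3), "widen")
})

test_that("both optimizer backends solve standard test problems", {
  for (m in c("bobyqa", "lbfgsb")) {
    r <- sccr:::.maximize(function(p) -(p - 2)^2, 0.5, 0, 5, m)
    expect_equal(r$par, 2, tolerance = 1e-5)
    expect_true(r$converged)
    rosen <- function(p) -(100 * (p[2] - p[1]^2)^2 + (1 - p[1])^2)
    r2 <- sccr:::.maximize(rosen, c(-1.2, 1), c(-2, -2), c(2, 2), m,
                           sccr:::.default_control(list(maxfun = 20000L,
                                                        maxit = 5000L,
                                                        rhoend = 1e-9)))
    expect_equal(r2$par, c(1, 1), tolerance = 1e-3)
  }
})

test_that("estimates pinned at a bound are reported as non-convergence", {
  r <- sccr:::.maximize(function(p) p, 0.5, 0, 1, "bobyqa")
  expect_false(r$converged)
  expect_match(r$message, "bound")
})

test_that("backends agree on a margin likelihood", {
  des <- small_design(n = 800)
  dat <- rsemicompeting(des, seed = 31)
  Z <- as.matrix(dat[c("Z1", "Z2")])
  fb <- fit_margin(dat$time2, dat$status2, Z, "exponential", "bobyqa")
  fl <- fit_margin(dat$time2, dat$status2, Z, "exponential", "lbfgsb")
  expect_equal(fb$beta, fl$beta, tolerance = 1e-3)
})

test_that("copula-stage search has dimension p + 1 and improves on its init", {
  des <- small_design(n = 400)
  dat <- rsemicompeting(des, seed = 32)
  spec <- des$spec
  Z <- as.matrix(dat[c("Z1", "Z2")])
  m1 <- fit_margin(dat$time1, dat$status1, Z, "exponential")
  m2 <- fit_margin(dat$time2, dat$status2, Z, "exponential")
  cop <- fit_copula_given_margins(dat, spec, m1, m2)
  expect_length(cop$b, 3)
  init_ll <- sc_loglik(pack_params(NULL, NULL, m1$beta, m2$beta,
                                   grid_search_init(function(b)
                                     sc_loglik(pack_params(NULL, NULL,
                                                           m1$beta, m2$beta,
                                                           b, spec),
                                               dat, spec),
                                     rep(-3, 3), rep(3, 3), 5), spec),
                       dat, spec)
  expect_gte(cop$loglik, init_ll)
})

test_that("two-step improves the joint likelihood over the two-stage plug-in", {
  for (cop in c("clayton", "gumbel")) {
    des <- small_design(copula = cop, n = 600)
    dat <- rsemicompeting(des, seed = 33)
    fit <- sccr_fit(dat, des$spec, procedure = "two_step")
    expect_gte(fit$loglik, fit$stage1$loglik)
    expect_equal(fit$aic, 2 * des$spec$n_par - 2 * fit$loglik)
  }
})

test_that("BOBYQA and L-BFGS-B two-step fits agree on a well-conditioned design", {
  des <- sccr_design(n = 1200)
  dat <- rsemicompeting(des, seed = 36)
  fb <- sccr_fit(dat, des$spec, optimizer = "bobyqa")
  fl <- sccr_fit(dat, des$spec, optimizer = "lbfgsb")
  expect_true(fb$converged && fl$converged)
  expect_lt(max(abs(fb$coefficients - fl$coefficients)), 1e-2)
})

test_that("two-stage and two-step nearly coincide at independence truth", {
  des <- sccr_design(copula = "normal", b = c(0, 0, 0), n = 1500,
                     censoring_upper = 0.56)
  dat <- rsemicompeting(des, seed = 34)
  fit <- sccr_fit(dat, des$spec)
  expect_lt(max(abs(fit$coefficients - fit$stage1$coefficients)), 1e-1)
  expect_lt(abs(fit$loglik - fit$stage1$loglik), 1)
})

test_that("all 12 copula-margin combinations fit without error on a fixture", {
  for (cop in copula_families) {
    for (mg in margin_families) {
      des <- sccr_design(copula = cop, margins = c(mg, mg), n = 250,
                         censoring_upper = if (mg == "exponential") 0.56
                                           else 1.0)
      dat <- rsemicompeting(des, seed = 35)
      fit <- sccr_fit(dat, des$spec, procedure = "two_stage",
                      control = list(hessian_r = 2L))
      expect_s3_class(fit, "sccr")
      expect_true(is.finite(fit$loglik))
    }
  }
})

test_that("Wald inference matches analytic results on known problems", {
  ## intercept-only uncensored exponential: SE(beta0) = 1/sqrt(n)
  set.seed(41)
  n <- 2000
  tt <- rexp(n, rate = 2)
  spec1 <- sccr_spec("clayton", "exponential", "exponential", character())
  fit <- fit_margin(tt, rep(1L, n), NULL, "exponential")
  w <- sccr:::.wald_from_fn(fit$objective, fit$par)
  expect_equal(unname(w$se), 1 / sqrt(n), tolerance = 1e-3)
  ## quadratic log-likelihood: SE equals the curvature scale exactly
  mu <- 0.7; sg <- 0.31
  wq <- sccr:::.wald_from_fn(function(p) -0.5 * ((p - mu) / sg)^2, mu)
  expect_equal(unname(wq$se), sg, tolerance = 1e-6)
  ## Hessian agrees with the analytic second derivative of the
  ## exponential margin likelihood: d2/dbeta2 = -sum(lambda * t)
  H <- numDeriv::hessian(function(p) fit$objective(p), fit$par)
  expect_equal(H[1, 1], -sum(exp(fit$par) * tt), tolerance = 1e-4)
})

test_that("degenerate Hessians flag standard errors as unavailable", {
  w <- sccr:::.wald_from_fn(function(p) 0 * p[1], 1)  # flat: H singular
  expect_false(w$ok)
  expect_true(all(is.na(w$se)))
})

test_that("hazard ratios and their two CI conventions", {
  des <- small_design(n = 500)
  dat <- rsemicompeting(des, seed = 51)
  fit <- sccr_fit(dat, des$spec)
  hr <- hazard_ratio_table(fit)
  expect_equal(nrow(hr), 4)  # 2 covariates x 2 margins
  expect_equal(hr$hr, exp(unname(
    fit$coefficients[c("NT.Z1", "NT.Z2", "T.Z1", "T.Z2")])))
  ## delta-method-on-HR-scale interval is symmetric around the estimate
  expect_equal(hr$hr - hr$lower, hr$upper - hr$hr, tolerance = 1e-10)
  hrl <- hazard_ratio_table(fit, type = "log")
  expect_true(all(hrl$lower > 0))
  cc <- copula_coef_table(fit)
  expect_equal(cc$estimate, unname(fit$coefficients[7:9]))
})

test_that("formula interface, methods and print work end to end", {
  des <- small_design(n = 400)
  dat <- rsemicompeting(des, seed = 52)
  fit <- sccr(SemiComp(time1, status1, time2, status2) ~ Z1 + Z2, dat,
              copula = "clayton")
  expect_s3_class(fit, "sccr")
  expect_named(coef(fit), des$spec$par_names)
  expect_equal(AIC(fit), fit$aic)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_output(print(summary(fit)), "Hazard ratios")
  s <- predict(fit, dat[1:5, ], times = 0.3)
  expect_true(all(s > 0 & s < 1))
  ## simulate from the fitted model round-trips the record invariants
  sim <- simulate(fit, nsim = 1, seed = 9, censoring_upper = 0.5)[[1]]
  expect_true(all(sim$time1 <= sim$time2))
  expect_true(all(sim$time1[sim$status1 == 0] == sim$time2[sim$status1 == 0]))
})
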