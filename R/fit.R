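## Estimation: grid-search initialization, pluggable bound-constrained
## optimizer backends (BOBYQA via minqa, L-BFGS-B via stats::optim),
## two-stage and two-step maximum likelihood, Wald inference and
## hazard-ratio tables.

.default_grid <- function(grid = list()) {
  utils::modifyList(list(coef = c(-3, 3), shape = c(0.1, 5), n = 5L), grid)
}

.default_bounds <- function(bounds = list()) {
  utils::modifyList(list(coef = c(-15, 15), shape = c(1e-3, 50)), bounds)
}

.default_control <- function(control = list()) {
  utils::modifyList(list(maxfun = 5000L, rhobeg = 0.25, rhoend = 1e-6,
                         npt = NULL, maxit = 1000L, factr = 1e7,
                         level = 0.95, hessian_r = 2L), control)
}

#' Grid-search initialization
#'
#' Evaluates an objective on the full Cartesian product of `n_grid` equally
#' spaced points per axis and returns the maximizing grid point.  Exactly
#' `n_grid^length(lower)` evaluations are performed; ties are broken by the
#' first occurrence in enumeration order.
#'
#' @param objective function of a parameter vector returning a scalar.
#' @param lower,upper numeric vectors of per-axis interval endpoints.
#' @param n_grid number of points per axis (`>= 2`).
#' @return the best grid point as a numeric vector.
#' @export
grid_search_init <- function(objective, lower, upper, n_grid = 5L) {
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("require lower < upper per axis", call. = FALSE)
  if (n_grid < 2) stop("n_grid must be >= 2", call. = FALSE)
  axes <- lapply(seq_along(lower),
                 function(j) seq(lower[j], upper[j], length.out = n_grid))
  pts <- as.matrix(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
  pts <- pts[, rev(seq_len(ncol(pts))), drop = FALSE]  # last axis fastest
  vals <- apply(pts, 1, objective)
  vals[!is.finite(vals)] <- -Inf
  if (all(vals == -Inf))
    stop("grid search: objective is -Inf on the entire grid; ",
         "widen the search ranges", call. = FALSE)
  unname(pts[which.max(vals), ])
}

## Maximizes fn over box constraints with the chosen backend.  Estimates
## pinned at a bound are reported as non-convergence ("what hitting bounds
## looks like"), never as success.
.maximize <- function(fn, init, lower, upper, method = "bobyqa",
                      control = .default_control()) {
  init <- pmin(pmax(init, lower + 1e-8), upper - 1e-8)
  ## rejected points are mapped to a large finite plateau: L-BFGS-B
  ## finite-differences the objective, so the raw 1e308-scale sentinel
  ## would overflow its gradient estimates
  neg <- function(p) {
    val <- fn(p)
    if (!is.finite(val) || val < -1e10) 1e10 else -val
  }
  v0 <- fn(init)
  res <- if (method == "bobyqa") {
    ## interpolation-point count: 2p+1 recommended default; a user value is
    ## honoured only where admissible for this subproblem's dimension
    d <- length(init)
    npt <- control$npt
    if (is.null(npt) || npt < d + 2 || npt > (d + 1) * (d + 2) / 2)
      npt <- 2L * d + 1L
    ctl <- list(npt = npt,
                rhobeg = min(control$rhobeg, min(upper - lower) / 4),
                rhoend = control$rhoend, maxfun = control$maxfun, iprint = 0L)
    r <- tryCatch(minqa::bobyqa(init, neg, lower = lower, upper = upper,
                                control = ctl),
                  error = function(e) e)
    if (inherits(r, "error"))
      list(par = init, value = v0, converged = FALSE, evals = NA_integer_,
           message = conditionMessage(r))
    else
      list(par = unname(r$par), value = -r$fval, converged = r$ierr == 0,
           evals = r$feval, message = if (r$ierr == 0) "" else r$msg)
  } else if (method == "lbfgsb") {
    r <- tryCatch(stats::optim(init, neg, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = control$maxit,
                                              factr = control$factr)),
                  error = function(e) e)
    if (inherits(r, "error"))
      list(par = init, value = v0, converged = FALSE, evals = NA_integer_,
           message = conditionMessage(r))
    else
      list(par = unname(r$par), value = -r$value,
           converged = r$convergence == 0, evals = unname(r$counts[1]),
           message = if (is.null(r$message)) "" else r$message)
  } else stop("unknown optimizer backend: ", method, call. = FALSE)
  ## optimizer contract: never worse than the starting point
  if (!is.finite(res$value) || res$value < v0) {
    res$par <- init; res$value <- v0
    res$converged <- FALSE
    res$message <- paste(res$message, "optimizer failed to improve on init")
  }
  tol <- 1e-6
  if (any(res$par <= lower + tol | res$par >= upper - tol)) {
    res$converged <- FALSE
    res$message <- paste(res$message, "estimate at parameter bound")
  }
  res
}

#' Fit one parametric margin by grid-initialized censored maximum likelihood
#'
#' Step 1(1) of the estimation algorithm: initializes `(alpha, beta)` by
#' [grid_search_init()] on the univariate right-censored log-likelihood and
#' refines by bound-constrained maximization.
#'
#' @param times,status observed times and 0/1 event indicators.
#' @param Z covariate matrix (`n x p`) or `NULL`.
#' @param family marginal family name.
#' @param optimizer `"bobyqa"` or `"lbfgsb"`.
#' @param grid,bounds,control optional settings, see [sccr()].
#' @return list with elements `alpha` (or `NULL`), `beta`, `loglik`,
#'   `converged`, `evals`, `message`.
#' @export
fit_margin <- function(times, status, Z, family = "exponential",
                       optimizer = "bobyqa", grid = list(), bounds = list(),
                       control = list()) {
  family <- .check_margin(family)
  grid <- .default_grid(grid); bounds <- .default_bounds(bounds)
  control <- .default_control(control)
  if (!all(status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (!is.null(Z)) Z <- as.matrix(Z)
  p1 <- if (is.null(Z)) 1L else ncol(Z) + 1L
  shp <- .margin_has_shape(family)
  mll <- .make_margin_loglik(family, times, status, Z)
  obj <- if (shp) function(par) mll(par[-1], par[1]) else function(par) mll(par)
  glo <- c(if (shp) grid$shape[1], rep(grid$coef[1], p1))
  ghi <- c(if (shp) grid$shape[2], rep(grid$coef[2], p1))
  init <- grid_search_init(obj, glo, ghi, grid$n)
  blo <- c(if (shp) bounds$shape[1], rep(bounds$coef[1], p1))
  bhi <- c(if (shp) bounds$shape[2], rep(bounds$coef[2], p1))
  res <- .maximize(obj, init, blo, bhi, optimizer, control)
  list(alpha = if (shp) res$par[1] else NULL,
       beta = if (shp) res$par[-1] else res$par,
       loglik = res$value, converged = res$converged, evals = res$evals,
       message = res$message, objective = obj,
       par = res$par)
}

#' Fit the copula link coefficients with margins plugged in
#'
#' Step 1(2): maximizes the joint semi-competing risks log-likelihood over
#' the copula coefficients `b` only, holding the marginal estimates fixed at
#' their plug-in values.  The search dimension is `p + 1` regardless of the
#' margin families.
#'
#' @param data validated data frame (see [sc_loglik()]).
#' @param spec an [sccr_spec()] object.
#' @param margin1,margin2 results of [fit_margin()] for the two margins.
#' @inheritParams fit_margin
#' @return list with elements `b`, `loglik`, `converged`, `evals`, `message`.
#' @export
fit_copula_given_margins <- function(data, spec, margin1, margin2,
                                     optimizer = "bobyqa", grid = list(),
                                     bounds = list(), control = list()) {
  grid <- .default_grid(grid); bounds <- .default_bounds(bounds)
  control <- .default_control(control)
  jll <- .make_joint_loglik(data, spec)
  k <- spec$p + 1L
  obj <- function(b)
    jll(pack_params(margin1$alpha, margin2$alpha, margin1$beta, margin2$beta,
                    b, spec))
  init <- grid_search_init(obj, rep(grid$coef[1], k), rep(grid$coef[2], k),
                           grid$n)
  res <- .maximize(obj, init, rep(bounds$coef[1], k), rep(bounds$coef[2], k),
                   optimizer, control)
  list(b = res$par, loglik = res$value, converged = res$converged,
       evals = res$evals, message = res$message)
}

#' Wald standard errors and confidence intervals
#'
#' Standard errors from the inverse negated numerical Hessian (central
#' differences with Richardson extrapolation) of the joint log-likelihood at
#' the estimate; confidence intervals are `estimate +/- z * SE`.  When the
#' Hessian is singular or not positive definite the standard errors are
#' flagged unavailable (`NA`).
#'
#' @param phi packed parameter estimate.
#' @param data validated data frame.
#' @param spec an [sccr_spec()] object.
#' @param level confidence level (default 0.95).
#' @return list with `se`, `ci` (two-column matrix), `vcov`, `ok`.
#' @export
wald_inference <- function(phi, data, spec, level = 0.95) {
  .wald_from_fn(.make_joint_loglik(data, spec), phi, level,
                names = spec$par_names)
}

.wald_from_fn <- function(fn, phi, level = 0.95, names = NULL, r = 2L) {
  H <- tryCatch(-numDeriv::hessian(fn, phi, method.args = list(r = r)),
                error = function(e) NULL)
  d <- length(phi)
  se <- rep(NA_real_, d); V <- matrix(NA_real_, d, d); ok <- FALSE
  if (!is.null(H) && all(is.finite(H))) {
    Vt <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (!is.null(Vt) && all(diag(Vt) > 0)) {
      V <- Vt; se <- sqrt(diag(Vt)); ok <- TRUE
    }
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = phi - z * se, upper = phi + z * se)
  if (!is.null(names)) {
    names(se) <- names; rownames(ci) <- names
    dimnames(V) <- list(names, names)
  }
  list(se = se, ci = ci, vcov = V, ok = ok)
}

## Blockwise-naive two-stage inference: each stage's own Hessian, ignoring
## plug-in variance propagation (this is what degrades two-stage coverage of
## the non-terminal margin under dependent censoring).
.two_stage_inference <- function(data, spec, m1, m2, cop, level, r = 2L) {
  jll <- .make_joint_loglik(data, spec)
  k <- spec$p + 1L
  w1 <- .wald_from_fn(m1$objective, m1$par, level, r = r)
  w2 <- .wald_from_fn(m2$objective, m2$par, level, r = r)
  bfn <- function(b) jll(pack_params(m1$alpha, m2$alpha, m1$beta, m2$beta,
                                     b, spec))
  wb <- .wald_from_fn(bfn, cop$b, level, r = r)
  se <- c(if (spec$has_shape1) w1$se[1], if (spec$has_shape2) w2$se[1],
          if (spec$has_shape1) w1$se[-1] else w1$se,
          if (spec$has_shape2) w2$se[-1] else w2$se,
          wb$se)
  names(se) <- spec$par_names
  ci <- cbind(lower = rbind(
                if (spec$has_shape1) w1$ci[1, , drop = FALSE],
                if (spec$has_shape2) w2$ci[1, , drop = FALSE],
                if (spec$has_shape1) w1$ci[-1, , drop = FALSE] else w1$ci,
                if (spec$has_shape2) w2$ci[-1, , drop = FALSE] else w2$ci,
                wb$ci)[, 1],
              upper = rbind(
                if (spec$has_shape1) w1$ci[1, , drop = FALSE],
                if (spec$has_shape2) w2$ci[1, , drop = FALSE],
                if (spec$has_shape1) w1$ci[-1, , drop = FALSE] else w1$ci,
                if (spec$has_shape2) w2$ci[-1, , drop = FALSE] else w2$ci,
                wb$ci)[, 2])
  rownames(ci) <- spec$par_names
  list(se = se, ci = ci, ok = w1$ok && w2$ok && wb$ok)
}

## Workhorse shared by the formula interface and the simulation engine.
.sccr_engine <- function(data, spec, procedure = "two_step",
                         optimizer = "bobyqa", grid = list(), bounds = list(),
                         control = list(), call = NULL,
                         stage1_inference = TRUE) {
  grid <- .default_grid(grid); bounds <- .default_bounds(bounds)
  control <- .default_control(control)
  level <- control$level
  jll <- .make_joint_loglik(data, spec)
  Z <- if (spec$p) as.matrix(data[, spec$covariates, drop = FALSE]) else NULL

  ## --- Step 1: margins separately, then copula coefficients --------------
  m1 <- fit_margin(data$time1, data$status1, Z, spec$margin_nonterminal,
                   optimizer, grid, bounds, control)
  m2 <- fit_margin(data$time2, data$status2, Z, spec$margin_terminal,
                   optimizer, grid, bounds, control)
  cop <- fit_copula_given_margins(data, spec, m1, m2, optimizer, grid,
                                  bounds, control)
  phi1 <- pack_params(m1$alpha, m2$alpha, m1$beta, m2$beta, cop$b, spec)
  ll1 <- jll(phi1)
  stage1_conv <- m1$converged && m2$converged && cop$converged
  inf1 <- if (stage1_inference)
    .two_stage_inference(data, spec, m1, m2, cop, level,
                         r = control$hessian_r)
  else list(se = NULL, ci = NULL, ok = NA)
  stage1 <- list(coefficients = phi1, se = inf1$se, ci = inf1$ci,
                 loglik = ll1, aic = aic(ll1, spec$n_par),
                 converged = stage1_conv, inference_ok = inf1$ok,
                 evals = c(margin1 = m1$evals, margin2 = m2$evals,
                           copula = cop$evals),
                 message = trimws(paste(m1$message, m2$message, cop$message)))

  if (procedure == "two_stage") {
    fit <- list(coefficients = phi1, se = inf1$se, ci = inf1$ci,
                vcov = NULL, loglik = ll1, aic = aic(ll1, spec$n_par),
                converged = stage1_conv, inference_ok = inf1$ok,
                message = stage1$message, evals = sum(stage1$evals))
  } else {
    ## --- Step 2: joint maximization over the full Phi --------------------
    blo <- c(if (spec$has_shape1) bounds$shape[1],
             if (spec$has_shape2) bounds$shape[1],
             rep(bounds$coef[1], 3L * (spec$p + 1L)))
    bhi <- c(if (spec$has_shape1) bounds$shape[2],
             if (spec$has_shape2) bounds$shape[2],
             rep(bounds$coef[2], 3L * (spec$p + 1L)))
    res <- .maximize(jll, unname(phi1), blo, bhi, optimizer, control)
    if (res$value < ll1) { res$par <- unname(phi1); res$value <- ll1 }
    phi2 <- stats::setNames(res$par, spec$par_names)
    inf2 <- .wald_from_fn(jll, unname(phi2), level, names = spec$par_names,
                          r = control$hessian_r)
    fit <- list(coefficients = phi2, se = inf2$se, ci = inf2$ci,
                vcov = inf2$vcov, loglik = res$value,
                aic = aic(res$value, spec$n_par),
                converged = res$converged, inference_ok = inf2$ok,
                message = if (res$converged) ""
                          else paste("step 2 not converged:", res$message),
                evals = sum(stage1$evals) + res$evals)
  }

  structure(c(fit,
              list(stage1 = stage1, spec = spec, procedure = procedure,
                   optimizer = optimizer, n = nrow(data), data = data,
                   grid = grid, bounds = bounds, level = level,
                   call = call)),
            class = "sccr")
}

#' Fit a copula-based semi-competing risks regression model
#'
#' Fits the joint model in which the bivariate survival function of the
#' non-terminal and terminal event times is
#' \eqn{S(t_1, t_2 | z) = C_\theta(S_1(t_1|z), S_2(t_2|z))} with a Clayton,
#' Frank, Gumbel or Gaussian survival copula, exponential/Weibull/Gompertz
#' margins with covariate effects on the rate through an exponential link,
#' and covariate effects on the dependence parameter through the
#' family-specific link of [link_theta()].
#'
#' Estimation follows a grid-initialized two-stage procedure (margins
#' separately by censored ML, then the copula coefficients with margins
#' plugged in), optionally followed — `procedure = "two_step"`, the default —
#' by a single joint maximization of the full likelihood started at the
#' two-stage estimate.  The two-stage estimator of the non-terminal margin
#' is biased under dependent censoring by the terminal event; the two-step
#' estimator corrects this.  Both a derivative-free BOBYQA backend and
#' L-BFGS-B are available; estimates ending on a parameter bound are
#' reported as non-convergence.
#'
#' @param formula a model formula whose left-hand side is a [SemiComp()]
#'   outcome and whose right-hand side gives the covariates, e.g.
#'   `SemiComp(time1, status1, time2, status2) ~ age + ccr5`.
#' @param data data frame containing the variables of `formula`.
#' @param copula copula family: `"clayton"`, `"frank"`, `"gumbel"`,
#'   `"normal"`.
#' @param margins length-2 character vector: the non-terminal and terminal
#'   marginal families (`"exponential"`, `"weibull"`, `"gompertz"`).
#' @param procedure `"two_step"` (joint ML from the two-stage start, the
#'   default) or `"two_stage"`.
#' @param optimizer `"bobyqa"` (default) or `"lbfgsb"`.
#' @param grid list overriding the grid-search settings: `coef` interval
#'   (default `c(-3, 3)`), `shape` interval (default `c(0.1, 5)`), points
#'   per axis `n` (default 5).
#' @param bounds list overriding the optimizer box constraints: `coef`
#'   (default `c(-15, 15)`), `shape` (default `c(1e-3, 50)`).
#' @param control list of optimizer/inference settings: `maxfun`, `rhobeg`,
#'   `rhoend`, `npt` (BOBYQA; interpolation points, default `2p + 1`),
#'   `maxit`, `factr` (L-BFGS-B), `level` (confidence level, default 0.95).
#' @return an object of class `"sccr"`: coefficients, Wald standard errors
#'   and confidence intervals, log-likelihood, AIC, convergence diagnostics,
#'   and the stage-1 (two-stage) results in `$stage1`.
#' @seealso [summary.sccr()], [hazard_ratio_table()], [sccr_sim_study()]
#' @examples
#' des <- sccr_design(n = 400)
#' dat <- rsemicompeting(des, seed = 1)
#' fit <- sccr(SemiComp(time1, status1, time2, status2) ~ Z1 + Z2, dat,
#'             copula = "clayton")
#' summary(fit)
#' @export
sccr <- function(formula, data, copula = "clayton",
                 margins = c("exponential", "exponential"),
                 procedure = c("two_step", "two_stage"),
                 optimizer = c("bobyqa", "lbfgsb"),
                 grid = list(), bounds = list(), control = list()) {
  procedure <- match.arg(procedure)
  optimizer <- match.arg(optimizer)
  if (length(margins) == 1) margins <- rep(margins, 2)
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  resp <- stats::model.response(mf)
  if (!inherits(resp, "SemiComp"))
    stop("the left-hand side of the formula must be a SemiComp() outcome",
         call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  covariates <- colnames(X)[-1]
  spec <- sccr_spec(copula, margins[1], margins[2], covariates)
  dat <- data.frame(time1 = resp[, 1], status1 = resp[, 2],
                    time2 = resp[, 3], status2 = resp[, 4],
                    check.names = FALSE)
  if (length(covariates))
    dat[covariates] <- as.data.frame(X[, -1, drop = FALSE])
  .sccr_engine(dat, spec, procedure, optimizer, grid, bounds, control,
               call = cl)
}

#' Data-frame interface to the semi-competing risks fit
#'
#' Same estimator as [sccr()] but taking a pre-validated data frame with
#' columns `time1, status1, time2, status2` plus covariates, and an
#' [sccr_spec()].  Used by the simulation engine and the command-line tools.
#'
#' @param data data frame as accepted by [sc_loglik()].
#' @param spec an [sccr_spec()] object.
#' @inheritParams sccr
#' @return an object of class `"sccr"`.
#' @export
sccr_fit <- function(data, spec, procedure = c("two_step", "two_stage"),
                     optimizer = c("bobyqa", "lbfgsb"), grid = list(),
                     bounds = list(), control = list()) {
  procedure <- match.arg(procedure)
  optimizer <- match.arg(optimizer)
  SemiComp(data$time1, data$status1, data$time2, data$status2)  # validates
  .sccr_engine(data, spec, procedure, optimizer, grid, bounds, control,
               call = match.call())
}

#' Hazard-ratio table for the fitted margins
#'
#' For the proportional-hazards margins used here the hazard ratio of
#' covariate `k` is `exp(beta_k)`.  The default confidence interval is the
#' delta method applied on the hazard-ratio scale, `HR +/- z * HR * SE(beta)`
#' (which can produce negative lower bounds); `type = "log"` gives the
#' exponentiated coefficient-scale interval instead.
#'
#' @param fit an `"sccr"` fit.
#' @param type `"delta"` (default) or `"log"`.
#' @param stage use the final estimates (`"final"`, default) or the stage-1
#'   two-stage estimates (`"stage1"`).
#' @return data frame with margin, covariate, hazard ratio and CI bounds.
#' @export
hazard_ratio_table <- function(fit, type = c("delta", "log"),
                               stage = c("final", "stage1")) {
  type <- match.arg(type)
  stage <- match.arg(stage)
  spec <- fit$spec
  est <- if (stage == "final") fit$coefficients else fit$stage1$coefficients
  se <- if (stage == "final") fit$se else fit$stage1$se
  z <- stats::qnorm(1 - (1 - fit$level) / 2)
  if (!spec$p)
    return(data.frame(margin = character(), covariate = character(),
                      hr = numeric(), lower = numeric(), upper = numeric()))
  rows <- lapply(c(nonterminal = "NT", terminal = "T"), function(tag) {
    nm <- paste0(tag, ".", spec$covariates)
    hr <- exp(est[nm]); s <- se[nm]
    if (type == "delta") {
      lo <- hr - z * hr * s; hi <- hr + z * hr * s
    } else {
      lo <- exp(est[nm] - z * s); hi <- exp(est[nm] + z * s)
    }
    data.frame(covariate = spec$covariates, hr = unname(hr),
               lower = unname(lo), upper = unname(hi))
  })
  out <- cbind(margin = rep(c("nonterminal", "terminal"),
                            each = spec$p),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Copula-coefficient table
#'
#' Estimates and Wald confidence intervals for the regression coefficients
#' of the dependence-parameter link.
#'
#' @inheritParams hazard_ratio_table
#' @return data frame with term, estimate and CI bounds.
#' @export
copula_coef_table <- function(fit, stage = c("final", "stage1")) {
  stage <- match.arg(stage)
  spec <- fit$spec
  est <- if (stage == "final") fit$coefficients else fit$stage1$coefficients
  ci <- if (stage == "final") fit$ci else fit$stage1$ci
  nm <- paste0("Copula.", c("(Intercept)", spec$covariates))
  data.frame(term = nm, estimate = unname(est[nm]),
             lower = unname(ci[nm, 1]), upper = unname(ci[nm, 2]),
             row.names = NULL)
}
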