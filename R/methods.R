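## S3 methods for the fitted model object.

#' @export
print.sccr <- function(x, digits = 4, ...) {
  cat("Copula-based semi-competing risks regression\n")
  cat("  copula:", x$spec$copula,
      " margins:", x$spec$margin_nonterminal, "/", x$spec$margin_terminal,
      "\n")
  cat("  procedure:", x$procedure, " optimizer:", x$optimizer,
      " n =", x$n, "\n")
  cat("  logLik:", format(x$loglik, digits = digits),
      " AIC:", format(x$aic, digits = digits),
      " converged:", x$converged, "\n\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summary of a semi-competing risks copula fit
#'
#' @param object an `"sccr"` fit.
#' @param hr_type confidence-interval convention for hazard ratios, see
#'   [hazard_ratio_table()].
#' @param ... unused.
#' @export
summary.sccr <- function(object, hr_type = "delta", ...) {
  z <- object$coefficients / object$se
  coefs <- data.frame(estimate = object$coefficients, se = object$se,
                      lower = object$ci[, 1], upper = object$ci[, 2],
                      z = z, p = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = coefs,
                 hr = hazard_ratio_table(object, type = hr_type),
                 copula = copula_coef_table(object)),
            class = "summary.sccr")
}

#' @export
print.summary.sccr <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (f$spec$copula == "frank") {
    th <- link_theta("frank",
                     unpack_params(f$coefficients, f$spec)$b,
                     as.matrix(f$data[, f$spec$covariates, drop = FALSE]))
    if (any(abs(th) < FRANK_INDEP_EPS))
      cat("\nNote: fitted Frank dependence parameter within 1e-8 of 0 for",
          sum(abs(th) < FRANK_INDEP_EPS),
          "subjects; evaluated by the independence limit.\n")
  }
  cat("\nStandard errors and ", 100 * f$level, "% Wald intervals",
      if (f$procedure == "two_stage") " (blockwise, stage-wise naive)",
      ":\n", sep = "")
  print(round(x$coefficients, digits))
  if (nrow(x$hr)) {
    cat("\nHazard ratios (per covariate, exp(beta)):\n")
    print(x$hr, digits = digits)
  }
  cat("\nCopula dependence coefficients:\n")
  print(x$copula, digits = digits)
  if (!isTRUE(f$inference_ok))
    cat("\nWarning: variance estimation unavailable",
        "(Hessian singular or not positive definite).\n")
  invisible(x)
}

#' @export
coef.sccr <- function(object, ...) object$coefficients

#' @export
vcov.sccr <- function(object, ...) object$vcov

#' @export
logLik.sccr <- function(object, ...) {
  structure(object$loglik, df = object$spec$n_par, nobs = object$n,
            class = "logLik")
}

#' @export
confint.sccr <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted marginal survival probabilities
#'
#' Evaluates the fitted marginal survival functions \eqn{S_1(t | z)} or
#' \eqn{S_2(t | z)} at new times and covariate values.
#'
#' @param object an `"sccr"` fit.
#' @param newdata data frame containing the model covariates; defaults to
#'   the fitted data.
#' @param times numeric vector of evaluation times (one per row of
#'   `newdata`, or recycled).
#' @param margin `"nonterminal"` or `"terminal"`.
#' @param ... unused.
#' @return numeric vector of survival probabilities.
#' @export
predict.sccr <- function(object, newdata = NULL, times,
                         margin = c("nonterminal", "terminal"), ...) {
  margin <- match.arg(margin)
  spec <- object$spec
  if (is.null(newdata)) newdata <- object$data
  Z <- as.matrix(newdata[, spec$covariates, drop = FALSE])
  pr <- unpack_params(object$coefficients, spec)
  if (margin == "nonterminal")
    margin_survival(spec$margin_nonterminal, times, rate_param(pr$beta1, Z),
                    pr$alpha1)
  else
    margin_survival(spec$margin_terminal, times, rate_param(pr$beta2, Z),
                    pr$alpha2)
}

#' Plot fitted marginal survival curves
#'
#' Draws the fitted non-terminal and terminal marginal survival functions at
#' a covariate profile (by default the column means of the fitted data).
#'
#' @param x an `"sccr"` fit.
#' @param z covariate profile (vector of length `p`); default column means.
#' @param tmax right end of the time axis; default the 99th percentile of
#'   observed second-event times.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sccr <- function(x, z = NULL, tmax = NULL, ...) {
  spec <- x$spec
  if (is.null(z))
    z <- colMeans(as.matrix(x$data[, spec$covariates, drop = FALSE]))
  if (is.null(tmax)) tmax <- stats::quantile(x$data$time2, 0.99)
  tt <- seq(0, tmax, length.out = 200)
  zm <- matrix(rep(z, each = length(tt)), nrow = length(tt))
  colnames(zm) <- spec$covariates
  nd <- as.data.frame(zm)
  s1 <- predict(x, nd, tt, "nonterminal")
  s2 <- predict(x, nd, tt, "terminal")
  graphics::plot(tt, s1, type = "l", ylim = c(0, 1), xlab = "time",
                 ylab = "marginal survival", ...)
  graphics::lines(tt, s2, lty = 2)
  graphics::legend("topright", c("non-terminal", "terminal"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Simulate semi-competing risks datasets from a fitted model
#'
#' Draws datasets from the fitted copula model at the estimated parameters,
#' using the fitted covariates and (by default) a censoring bound calibrated
#' to the observed terminal censoring rate.
#'
#' @param object an `"sccr"` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param censoring_upper upper bound of the uniform censoring law; default
#'   calibrated to the observed terminal censoring rate.
#' @param ... unused.
#' @return a list of `nsim` data frames.
#' @export
simulate.sccr <- function(object, nsim = 1, seed = NULL,
                          censoring_upper = NULL, ...) {
  spec <- object$spec
  pr <- unpack_params(object$coefficients, spec)
  Zobs <- as.matrix(object$data[, spec$covariates, drop = FALSE])
  des <- sccr_design(copula = spec$copula,
                     margins = c(spec$margin_nonterminal,
                                 spec$margin_terminal),
                     beta_nt = pr$beta1, beta_t = pr$beta2, b = pr$b,
                     alpha_nt = pr$alpha1, alpha_t = pr$alpha2,
                     n = object$n,
                     censoring_upper = censoring_upper,
                     target_terminal_censoring =
                       mean(object$data$status2 == 0),
                     covariate_sampler = function(n)
                       Zobs[sample.int(nrow(Zobs), n, replace = TRUE), ,
                            drop = FALSE],
                     covariate_names = spec$covariates)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  lapply(seq_len(nsim), function(i) rsemicompeting(des, seed = seed + i - 1))
}
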