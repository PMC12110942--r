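## Parametric marginal survival models: exponential, Weibull, Gompertz.
## Covariates act on the rate/scale parameter through an exponential link,
## lambda = exp(beta0 + beta' z); shape parameters are constant across
## subjects.  All three margins are proportional-hazards models, so
## exp(beta_k) is a hazard ratio.

MARGIN_FAMILIES <- c("exponential", "weibull", "gompertz")

## Large negative sentinel returned for inadmissible parameters so that
## bound-constrained optimizers can reject the point monotonically.
NEG_SENTINEL <- -.Machine$double.xmax

.check_margin <- function(family) match.arg(family, MARGIN_FAMILIES)

.margin_has_shape <- function(family) family %in% c("weibull", "gompertz")

.check_shape <- function(family, alpha) {
  if (.margin_has_shape(family)) {
    if (is.null(alpha) || !is.finite(alpha) || alpha <= 0)
      stop(family, " margin requires a positive shape parameter alpha",
           call. = FALSE)
  } else if (!is.null(alpha)) {
    stop("exponential margin carries no shape parameter", call. = FALSE)
  }
  invisible(NULL)
}

#' Rate parameter under the exponential link
#'
#' Computes \eqn{\lambda = \exp(\beta_0 + \beta_1 Z_1 + \dots + \beta_p Z_p)},
#' the covariate-dependent rate (exponential, Gompertz) or scale (Weibull)
#' parameter of the marginal survival model.
#'
#' @param beta coefficient vector of length `p + 1`, intercept first.
#' @param z covariate vector of length `p`, or an `n x p` matrix.
#' @return positive rate parameter(s), one per subject.
#' @export
rate_param <- function(beta, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  z <- as.matrix(z)
  if (length(beta) != ncol(z) + 1)
    stop("length(beta) must equal ncol(z) + 1", call. = FALSE)
  exp(drop(cbind(1, z) %*% beta))
}

## log survival, no validation; t >= 0, lambda > 0 vectors
.margin_logsurv <- function(family, t, lambda, alpha = NULL) {
  switch(family,
    exponential = -lambda * t,
    weibull     = -lambda * t^alpha,
    gompertz    = -lambda / alpha * expm1(alpha * t)
  )
}

## log density, no validation; t > 0
.margin_logdens <- function(family, t, lambda, alpha = NULL) {
  switch(family,
    exponential = log(lambda) - lambda * t,
    weibull     = log(lambda) + log(alpha) + (alpha - 1) * log(t) -
                    lambda * t^alpha,
    gompertz    = log(lambda) + alpha * t - lambda / alpha * expm1(alpha * t)
  )
}

#' Marginal survival function
#'
#' \eqn{S(t \mid z) = e^{-\lambda t}} (exponential),
#' \eqn{e^{-\lambda t^\alpha}} (Weibull) or
#' \eqn{e^{-(\lambda/\alpha)(e^{\alpha t} - 1)}} (Gompertz), with
#' \eqn{\lambda} from [rate_param()].
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`.
#' @param t nonnegative time(s).
#' @param lambda positive rate/scale parameter(s).
#' @param alpha shape parameter (Weibull/Gompertz only).
#' @return survival probabilities in \eqn{(0, 1]}.
#' @export
margin_survival <- function(family, t, lambda, alpha = NULL) {
  family <- .check_margin(family)
  .check_shape(family, alpha)
  if (any(t < 0)) stop("negative times", call. = FALSE)
  exp(.margin_logsurv(family, t, lambda, alpha))
}

#' Marginal density function
#'
#' The density \eqn{f(t \mid z) = -dS/dt} of the marginal survival model.
#' For the Weibull with shape \eqn{\alpha < 1} the density is unbounded at
#' the origin and `t = 0` is rejected.
#'
#' @inheritParams margin_survival
#' @param t positive time(s).
#' @export
margin_density <- function(family, t, lambda, alpha = NULL) {
  family <- .check_margin(family)
  .check_shape(family, alpha)
  if (any(t < 0)) stop("negative times", call. = FALSE)
  if (any(t == 0) && family == "weibull" && alpha < 1)
    stop("Weibull density with shape < 1 is unbounded at t = 0", call. = FALSE)
  exp(.margin_logdens(family, t, lambda, alpha))
}

#' Marginal survival quantile (inverse survival function)
#'
#' Returns the time \eqn{t} with \eqn{S(t \mid z) = s}; used by the
#' simulator to transform copula-coupled uniform survival probabilities into
#' event times.  Closed forms exist for all three families.
#'
#' @inheritParams margin_survival
#' @param s survival probabilities in \eqn{(0, 1]}.
#' @export
margin_quantile <- function(family, s, lambda, alpha = NULL) {
  family <- .check_margin(family)
  .check_shape(family, alpha)
  if (any(s <= 0 | s > 1)) stop("s must lie in (0, 1]", call. = FALSE)
  switch(family,
    exponential = -log(s) / lambda,
    weibull     = (-log(s) / lambda)^(1 / alpha),
    gompertz    = log1p(-alpha * log(s) / lambda) / alpha
  )
}

#' Right-censored log-likelihood of one parametric margin
#'
#' The univariate censored log-likelihood
#' \eqn{\sum_i d_i \log f(t_i \mid z_i) + (1 - d_i) \log S(t_i \mid z_i)}
#' maximized in Step 1 of the two-stage procedure.  Inadmissible parameters
#' (non-finite, or shape \eqn{\le 0}) return a large negative sentinel
#' rather than raising, so optimizers can reject them.
#'
#' @inheritParams margin_survival
#' @param times observed times (nonnegative).
#' @param status event indicators in \{0, 1\}.
#' @param Z covariate matrix (`n x p`), or `NULL` for intercept-only.
#' @param beta coefficient vector of length `p + 1`.
#' @param alpha shape parameter (Weibull/Gompertz only).
#' @return scalar log-likelihood.
#' @export
margin_censored_loglik <- function(family, times, status, Z, beta,
                                   alpha = NULL) {
  family <- .check_margin(family)
  n <- length(times)
  if (length(status) != n) stop("length mismatch", call. = FALSE)
  if (!all(status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop("length mismatch", call. = FALSE)
  if (length(beta) != ncol(Z) + 1)
    stop("length(beta) must equal ncol(Z) + 1", call. = FALSE)
  if (any(!is.finite(beta)) ||
      (.margin_has_shape(family) &&
         (is.null(alpha) || !is.finite(alpha) || alpha <= 0)))
    return(NEG_SENTINEL)
  .make_margin_loglik(family, times, status, Z)(beta, alpha)
}

## Fast closure form of the censored margin log-likelihood: data-dependent
## quantities precomputed once, no per-call validation.
.make_margin_loglik <- function(family, times, status, Z) {
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = length(times), ncol = 0)
  X1 <- cbind(1, as.matrix(Z))
  d <- status == 1
  td <- times[d]; tc <- times[!d]
  Xd <- X1[d, , drop = FALSE]; Xc <- X1[!d, , drop = FALSE]
  shp <- .margin_has_shape(family)
  function(beta, alpha = NULL) {
    if (any(!is.finite(beta)) ||
        (shp && (is.null(alpha) || !is.finite(alpha) || alpha <= 0)))
      return(NEG_SENTINEL)
    ll <- sum(.margin_logdens(family, td, exp(drop(Xd %*% beta)), alpha)) +
      sum(.margin_logsurv(family, tc, exp(drop(Xc %*% beta)), alpha))
    if (!is.finite(ll)) NEG_SENTINEL else ll
  }
}
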