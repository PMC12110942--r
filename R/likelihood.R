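## Joint semi-competing-risks log-likelihood and the parameter-vector
## packing shared by every estimation routine.
##
## Observables per subject: X = min(T1, T2, Ct) with d1 = 1{T1 < min(T2, Ct)},
## Y = min(T2, Ct) with d2 = 1{T2 < Ct}.  The four censoring patterns
## contribute, with u = S1(x|z), v = S2(y|z) and theta = link(b, z):
##   (1,1): log c_theta(u, v) + log f1(x) + log f2(y)
##   (1,0): log dC/du (u, v)  + log f1(x)
##   (0,1): log dC/dv (u, v)  + log f2(y)
##   (0,0): log C(u, v)
## The copula is always evaluated at the pair of observed times; when the
## terminal event comes first, x = y by construction.

## Survival probabilities are clamped to this band inside likelihood
## evaluations to prevent log(0)/overflow; the exported cdf is not clamped.
UV_CLAMP <- 1e-12

#' Semi-competing risks response object
#'
#' Packs the four observed outcome columns of semi-competing risks data into
#' a response matrix for use on the left-hand side of the model formula of
#' [sccr()]: time to first event `x`, non-terminal event indicator `d1`,
#' time to second event `y`, terminal event indicator `d2`.  Validates the
#' semi-competing ordering invariants `0 <= x <= y`, binary indicators, and
#' `d1 == 0` implies `x == y` (if the non-terminal event is not observed
#' first, the first observed time is the terminal/censoring time).
#'
#' @param x,y observed times to first and second event.
#' @param d1,d2 binary indicators for the non-terminal and terminal event.
#' @return a numeric matrix of class `"SemiComp"` with columns
#'   `time1, status1, time2, status2`.
#' @export
SemiComp <- function(x, d1, y, d2) {
  n <- length(x)
  if (length(d1) != n || length(y) != n || length(d2) != n)
    stop("SemiComp: all four arguments must have the same length",
         call. = FALSE)
  if (anyNA(x) || anyNA(d1) || anyNA(y) || anyNA(d2))
    stop("SemiComp: missing values in outcome columns", call. = FALSE)
  bad <- which(x < 0 | x > y)
  if (length(bad))
    stop("SemiComp: rows violate 0 <= time1 <= time2: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (!all(d1 %in% c(0, 1)) || !all(d2 %in% c(0, 1)))
    stop("SemiComp: status indicators must be 0/1", call. = FALSE)
  bad <- which(d1 == 0 & x != y)
  if (length(bad))
    stop("SemiComp: rows with status1 == 0 must have time1 == time2: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  m <- cbind(time1 = as.numeric(x), status1 = as.numeric(d1),
             time2 = as.numeric(y), status2 = as.numeric(d2))
  class(m) <- c("SemiComp", "matrix")
  m
}

#' Model specification for a copula semi-competing risks regression
#'
#' Combines a copula family, two marginal survival families and the
#' covariate names into the object that defines the packed parameter-vector
#' layout `Phi = (alpha1?, alpha2?, beta1, beta2, b)` (shapes first, when the
#' corresponding margin has one; then non-terminal, terminal and copula
#' coefficient blocks, each of length `p + 1` with the intercept first).
#'
#' @param copula copula family name.
#' @param margin_nonterminal,margin_terminal marginal family names.
#' @param covariates character vector of covariate names (may be empty).
#' @return an object of class `"sccr_spec"`.
#' @export
sccr_spec <- function(copula = "clayton",
                      margin_nonterminal = "exponential",
                      margin_terminal = "exponential",
                      covariates = character()) {
  copula <- .check_family(copula)
  m1 <- .check_margin(margin_nonterminal)
  m2 <- .check_margin(margin_terminal)
  p <- length(covariates)
  has1 <- .margin_has_shape(m1); has2 <- .margin_has_shape(m2)
  cn <- c("(Intercept)", covariates)
  par_names <- c(if (has1) "alpha_NT", if (has2) "alpha_T",
                 paste0("NT.", cn), paste0("T.", cn), paste0("Copula.", cn))
  structure(list(copula = copula, margin_nonterminal = m1,
                 margin_terminal = m2, covariates = covariates, p = p,
                 has_shape1 = has1, has_shape2 = has2,
                 n_par = has1 + has2 + 3 * (p + 1), par_names = par_names),
            class = "sccr_spec")
}

#' @export
print.sccr_spec <- function(x, ...) {
  cat("Semi-competing risks copula model specification\n")
  cat("  copula:             ", x$copula, "\n")
  cat("  non-terminal margin:", x$margin_nonterminal, "\n")
  cat("  terminal margin:    ", x$margin_terminal, "\n")
  cat("  covariates:         ",
      if (x$p) paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  parameters:         ", x$n_par, "\n")
  invisible(x)
}

#' Pack model parameters into the flat vector Phi
#'
#' @param alpha1,alpha2 shape parameters (or `NULL` for exponential margins).
#' @param beta1,beta2 margin coefficient vectors, length `p + 1`.
#' @param b copula link coefficient vector, length `p + 1`.
#' @param spec an [sccr_spec()] object.
#' @return named numeric vector of length `spec$n_par`.
#' @export
pack_params <- function(alpha1 = NULL, alpha2 = NULL, beta1, beta2, b, spec) {
  k <- spec$p + 1
  if (length(beta1) != k || length(beta2) != k || length(b) != k)
    stop("coefficient blocks must have length p + 1", call. = FALSE)
  if (spec$has_shape1 && length(alpha1) != 1)
    stop("alpha1 required for a ", spec$margin_nonterminal,
         " non-terminal margin", call. = FALSE)
  if (spec$has_shape2 && length(alpha2) != 1)
    stop("alpha2 required for a ", spec$margin_terminal,
         " terminal margin", call. = FALSE)
  if (!spec$has_shape1 && !is.null(alpha1))
    stop("alpha1 supplied for an exponential non-terminal margin",
         call. = FALSE)
  if (!spec$has_shape2 && !is.null(alpha2))
    stop("alpha2 supplied for an exponential terminal margin", call. = FALSE)
  phi <- c(if (spec$has_shape1) alpha1, if (spec$has_shape2) alpha2,
           beta1, beta2, b)
  stats::setNames(as.numeric(phi), spec$par_names)
}

#' Unpack the flat parameter vector Phi into model components
#'
#' Exact inverse of [pack_params()].
#'
#' @param phi numeric vector of length `spec$n_par`.
#' @param spec an [sccr_spec()] object.
#' @return list with elements `alpha1`, `alpha2` (possibly `NULL`), `beta1`,
#'   `beta2`, `b`.
#' @export
unpack_params <- function(phi, spec) {
  if (length(phi) != spec$n_par)
    stop("phi has length ", length(phi), ", expected ", spec$n_par,
         call. = FALSE)
  k <- spec$p + 1
  i <- 0L
  alpha1 <- if (spec$has_shape1) phi[[i <- i + 1L]] else NULL
  alpha2 <- if (spec$has_shape2) phi[[i <- i + 1L]] else NULL
  list(alpha1 = alpha1, alpha2 = alpha2,
       beta1 = unname(phi[i + seq_len(k)]),
       beta2 = unname(phi[i + k + seq_len(k)]),
       b     = unname(phi[i + 2L * k + seq_len(k)]))
}

## Builds a fast closure evaluating the joint log-likelihood for a fixed
## dataset; all data-dependent quantities are precomputed once.
.make_joint_loglik <- function(data, spec) {
  x <- data$time1; y <- data$time2
  d1 <- data$status1; d2 <- data$status2
  n <- length(x)
  Z <- as.matrix(data[, spec$covariates, drop = FALSE])
  X1 <- cbind(1, Z)   # design matrix, shared by all three coefficient blocks
  i11 <- which(d1 == 1 & d2 == 1)
  i10 <- which(d1 == 1 & d2 == 0)
  i01 <- which(d1 == 0 & d2 == 1)
  i00 <- which(d1 == 0 & d2 == 0)
  fam <- spec$copula
  m1 <- spec$margin_nonterminal; m2 <- spec$margin_terminal
  clamp <- function(p) {
    p[p < UV_CLAMP] <- UV_CLAMP
    p[p > 1 - UV_CLAMP] <- 1 - UV_CLAMP
    p
  }

  function(phi) {
    if (any(!is.finite(phi))) return(NEG_SENTINEL)
    pr <- unpack_params(phi, spec)
    if ((spec$has_shape1 && pr$alpha1 <= 0) ||
        (spec$has_shape2 && pr$alpha2 <= 0)) return(NEG_SENTINEL)
    lambda1 <- exp(drop(X1 %*% pr$beta1))
    lambda2 <- exp(drop(X1 %*% pr$beta2))
    eta <- drop(X1 %*% pr$b)
    theta <- switch(fam,
      clayton = exp(eta),
      frank   = eta,
      gumbel  = exp(eta) + 1,
      normal  = tanh(eta))
    if (fam == "clayton" && any(theta <= 0)) return(NEG_SENTINEL)
    u <- clamp(exp(.margin_logsurv(m1, x, lambda1, pr$alpha1)))
    v <- clamp(exp(.margin_logsurv(m2, y, lambda2, pr$alpha2)))
    ll <- 0
    if (length(i11))
      ll <- ll + sum(.cop_logdensity(fam, u[i11], v[i11], theta[i11])) +
        sum(.margin_logdens(m1, x[i11], lambda1[i11], pr$alpha1)) +
        sum(.margin_logdens(m2, y[i11], lambda2[i11], pr$alpha2))
    if (length(i10))
      ll <- ll + sum(.cop_loghfun(fam, u[i10], v[i10], theta[i10], 1L)) +
        sum(.margin_logdens(m1, x[i10], lambda1[i10], pr$alpha1))
    if (length(i01))
      ll <- ll + sum(.cop_loghfun(fam, u[i01], v[i01], theta[i01], 2L)) +
        sum(.margin_logdens(m2, y[i01], lambda2[i01], pr$alpha2))
    if (length(i00))
      ll <- ll + sum(.cop_logcdf(fam, u[i00], v[i00], theta[i00]))
    if (!is.finite(ll)) NEG_SENTINEL else ll
  }
}

#' Joint semi-competing risks log-likelihood
#'
#' Evaluates the joint log-likelihood of the copula semi-competing risks
#' regression model at a packed parameter vector.  Each subject contributes
#' one of four terms according to the censoring pattern `(d1, d2)`: the
#' full bivariate density, an h-function times a marginal density (one event
#' observed), or the joint survival copula CDF (both censored).  Survival
#' probabilities are clamped to `[1e-12, 1 - 1e-12]` before entering the
#' copula kernels.  Numerically inadmissible parameters return a large
#' negative sentinel instead of raising, so optimizers can reject them;
#' structural errors (dimension mismatch, empty data) raise.
#'
#' @param phi packed parameter vector, see [pack_params()].
#' @param data data frame with columns `time1, status1, time2, status2` and
#'   the covariates named in `spec`.
#' @param spec an [sccr_spec()] object.
#' @return scalar log-likelihood.
#' @export
sc_loglik <- function(phi, data, spec) {
  if (!nrow(data)) stop("empty data", call. = FALSE)
  miss <- setdiff(c("time1", "status1", "time2", "status2", spec$covariates),
                  names(data))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  .make_joint_loglik(data, spec)(phi)
}

#' Akaike information criterion
#'
#' `2k - 2 * loglik` for a model with `k` free parameters.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (`k >= 1`).
#' @export
aic <- function(loglik, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  2 * k - 2 * loglik
}
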