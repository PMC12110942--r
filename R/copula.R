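## Copula kernels: CDF, density, h-functions (conditional CDFs), inverse
## conditionals, dependence-parameter links and Kendall's tau for the four
## supported families.  All likelihood-facing kernels work on the log scale.

COPULA_FAMILIES <- c("clayton", "frank", "gumbel", "normal")

## Frank is evaluated by its independence limit when |theta| falls below this
## threshold: the closed form is 0/0 at theta = 0 and the identity link passes
## through 0, so the optimizer must be able to cross it smoothly.
FRANK_INDEP_EPS <- 1e-8

## Numerical guard for the Gaussian correlation inside likelihood evaluations.
NORMAL_RHO_MAX <- 1 - 1e-8

.check_family <- function(family) {
  match.arg(family, COPULA_FAMILIES)
}

.theta_range_msg <- function(family) {
  switch(family,
    clayton = "clayton requires theta in (0, Inf)",
    frank   = "frank requires theta in R \\ {0}",
    gumbel  = "gumbel requires theta in [1, Inf)",
    normal  = "normal requires theta in [-1, 1]"
  )
}

.theta_admissible <- function(family, theta) {
  switch(family,
    clayton = theta > 0,
    frank   = theta != 0,
    gumbel  = theta >= 1,
    normal  = theta >= -1 & theta <= 1
  )
}

.check_theta <- function(family, theta) {
  if (any(!is.finite(theta)))
    stop("non-finite theta", call. = FALSE)
  if (any(!.theta_admissible(family, theta)))
    stop(.theta_range_msg(family), call. = FALSE)
}

.check_uv <- function(u, v, open = FALSE, upper_closed = TRUE) {
  if (any(is.na(u)) || any(is.na(v)))
    stop("NaN/NA values in u or v", call. = FALSE)
  lo_ok <- if (open) (u > 0 & v > 0) else (u >= 0 & v >= 0)
  hi_ok <- if (open && !upper_closed) (u < 1 & v < 1) else (u <= 1 & v <= 1)
  if (any(!(lo_ok & hi_ok)))
    stop(if (open && !upper_closed) "u and v must lie in the open interval (0, 1)"
         else "u and v must lie in [0, 1]", call. = FALSE)
}

## ---- Gauss-Legendre nodes for the Gaussian-copula CDF -----------------------

## Nodes/weights on [0, 1], computed once at load via the Golub-Welsch
## eigenvalue method (symmetric tridiagonal Jacobi matrix).
.gauss_legendre_01 <- function(k) {
  i <- seq_len(k - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}

.bvn_gl <- .gauss_legendre_01(48)

## Bivariate standard normal CDF P(X <= x, Y <= y) with correlation rho,
## vectorized over all arguments.  Uses the single-integral representation
## Phi2(x, y, rho) = Phi(x) Phi(y) + (1/2pi) Int_0^rho phi2(x, y; r) dr
## evaluated by fixed Gauss-Legendre quadrature after substituting r = rho t.
pbvnorm <- function(x, y, rho) {
  n <- max(length(x), length(y), length(rho))
  x <- rep_len(x, n); y <- rep_len(y, n); rho <- rep_len(rho, n)
  base <- stats::pnorm(x) * stats::pnorm(y)
  out <- base
  nz <- which(rho != 0 & is.finite(x) & is.finite(y))
  if (length(nz)) {
    xs <- x[nz]; ys <- y[nz]; rs <- rho[nz]
    tk <- .bvn_gl$nodes; wk <- .bvn_gl$weights
    ## n x K matrices of r = rho * t_k
    r <- outer(rs, tk)
    omr2 <- 1 - r * r
    integ <- exp(-(xs^2 - 2 * r * xs * ys + ys^2) / (2 * omr2)) / sqrt(omr2)
    out[nz] <- base[nz] + rs / (2 * pi) * drop(integ %*% wk)
  }
  ## handle infinite margins: Phi2 reduces to the univariate CDF or 0
  ninf <- x == -Inf | y == -Inf
  out[ninf] <- 0
  out[x == Inf] <- stats::pnorm(y[x == Inf])
  out[y == Inf] <- stats::pnorm(x[y == Inf])
  pmin(pmax(out, 0), 1)
}

## ---- log-scale kernels (no validation; inputs in (0,1), theta admissible) ---

.cop_logcdf <- function(family, u, v, theta) {
  lu <- log(u); lv <- log(v)
  switch(family,
    clayton = {
      a <- expm1(-theta * lu) + expm1(-theta * lv)
      -log1p(a) / theta
    },
    frank = {
      out <- lu + lv
      i <- abs(theta) >= FRANK_INDEP_EPS
      if (any(i)) {
        th <- theta[i]
        s <- -expm1(-th)
        gu <- -expm1(-th * u[i]); gv <- -expm1(-th * v[i])
        out[i] <- log(-log1p(-gu * gv / s) / th)
      }
      out
    },
    gumbel = {
      lx <- log(-lu); ly <- log(-lv)
      m <- pmax(lx, ly); mn <- pmin(lx, ly)
      logS <- theta * m + log1p(exp(theta * (mn - m)))
      -exp(logS / theta)
    },
    normal = {
      log(pbvnorm(stats::qnorm(u), stats::qnorm(v), theta))
    }
  )
}

.cop_logdensity <- function(family, u, v, theta) {
  lu <- log(u); lv <- log(v)
  switch(family,
    clayton = {
      a <- expm1(-theta * lu) + expm1(-theta * lv)
      log1p(theta) - (theta + 1) * (lu + lv) - (1 / theta + 2) * log1p(a)
    },
    frank = {
      out <- numeric(length(u)) # independence: log c = 0
      i <- abs(theta) >= FRANK_INDEP_EPS
      if (any(i)) {
        th <- theta[i]
        s <- -expm1(-th)
        gu <- -expm1(-th * u[i]); gv <- -expm1(-th * v[i])
        D <- s - gu * gv
        out[i] <- log(th * s) - th * (u[i] + v[i]) - 2 * log(abs(D))
      }
      out
    },
    gumbel = {
      x <- -lu; y <- -lv
      lx <- log(x); ly <- log(y)
      m <- pmax(lx, ly); mn <- pmin(lx, ly)
      logS <- theta * m + log1p(exp(theta * (mn - m)))
      logA <- logS / theta
      A <- exp(logA)
      -A + (theta - 1) * (lx + ly) + (2 - 2 * theta) * logA +
        log1p((theta - 1) / A) + x + y
    },
    normal = {
      rho <- pmin(pmax(theta, -NORMAL_RHO_MAX), NORMAL_RHO_MAX)
      x <- stats::qnorm(u); y <- stats::qnorm(v)
      omr2 <- 1 - rho * rho
      -0.5 * log(omr2) - (rho^2 * (x^2 + y^2) - 2 * rho * x * y) / (2 * omr2)
    }
  )
}

## log of h(v | u) = dC/du when wrt = 1L, log of dC/dv when wrt = 2L.
.cop_loghfun <- function(family, u, v, theta, wrt = 1L) {
  if (wrt == 2L) return(.cop_loghfun(family, v, u, theta, 1L))
  lu <- log(u); lv <- log(v)
  switch(family,
    clayton = {
      a <- expm1(-theta * lu) + expm1(-theta * lv)
      -(theta + 1) * lu - (1 / theta + 1) * log1p(a)
    },
    frank = {
      out <- lv
      i <- abs(theta) >= FRANK_INDEP_EPS
      if (any(i)) {
        th <- theta[i]
        s <- -expm1(-th)
        gu <- -expm1(-th * u[i]); gv <- -expm1(-th * v[i])
        out[i] <- -th * u[i] + log(gv / (s - gu * gv))
      }
      out
    },
    gumbel = {
      x <- -lu
      lx <- log(x); ly <- log(-lv)
      m <- pmax(lx, ly); mn <- pmin(lx, ly)
      logS <- theta * m + log1p(exp(theta * (mn - m)))
      logA <- logS / theta
      -exp(logA) + (1 - theta) * (logA - lx) + x
    },
    normal = {
      rho <- pmin(pmax(theta, -NORMAL_RHO_MAX), NORMAL_RHO_MAX)
      x <- stats::qnorm(u); y <- stats::qnorm(v)
      stats::pnorm((y - rho * x) / sqrt(1 - rho * rho), log.p = TRUE)
    }
  )
}

## ---- exported surface -------------------------------------------------------

#' Copula distribution function
#'
#' Evaluates the copula CDF \eqn{C_\theta(u, v)} for one of the four supported
#' families.  The families and their admissible dependence parameters are
#' Clayton (\eqn{\theta > 0}), Frank (\eqn{\theta \ne 0}), Gumbel
#' (\eqn{\theta \ge 1}) and normal (Gaussian, \eqn{-1 \le \theta \le 1}).
#' Frank values with \eqn{|\theta| < 10^{-8}} are evaluated by the
#' independence limit \eqn{C(u, v) = uv}.
#'
#' @param family one of `"clayton"`, `"frank"`, `"gumbel"`, `"normal"`.
#' @param u,v evaluation points in \eqn{[0, 1]}; recycled to common length.
#' @param theta dependence parameter(s), admissible for `family`.
#' @return numeric vector of copula CDF values in \eqn{[0, 1]}.
#' @examples
#' copula_cdf("clayton", 0.5, 0.5, theta = 1)  # 1/3
#' copula_cdf("gumbel", exp(-1), exp(-1), theta = 2)  # exp(-sqrt(2))
#' @export
copula_cdf <- function(family, u, v, theta) {
  family <- .check_family(family)
  .check_theta(family, theta)
  .check_uv(u, v)
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  theta <- rep_len(as.numeric(theta), n)
  out <- numeric(n)
  ## boundary cases are exact by the copula boundary conditions
  b0 <- u == 0 | v == 0
  bu <- v == 1 & !b0
  bv <- u == 1 & !b0
  inner <- !(b0 | bu | bv)
  out[bu] <- u[bu]
  out[bv] <- v[bv]
  if (any(inner))
    out[inner] <- exp(.cop_logcdf(family, u[inner], v[inner], theta[inner]))
  out
}

#' Copula density
#'
#' Evaluates the copula density \eqn{c_\theta(u, v) = \partial^2 C / \partial
#' u \partial v} on the open unit square.
#'
#' @inheritParams copula_cdf
#' @param u,v evaluation points in the open interval \eqn{(0, 1)}.
#' @return numeric vector of nonnegative density values.
#' @export
copula_density <- function(family, u, v, theta) {
  family <- .check_family(family)
  .check_theta(family, theta)
  .check_uv(u, v, open = TRUE, upper_closed = FALSE)
  n <- max(length(u), length(v), length(theta))
  exp(.cop_logdensity(family, rep_len(as.numeric(u), n),
                      rep_len(as.numeric(v), n), rep_len(as.numeric(theta), n)))
}

#' Copula h-function (conditional distribution function)
#'
#' The partial derivatives \eqn{\partial C/\partial u} (`conditioned =
#' "first"`) and \eqn{\partial C/\partial v} (`conditioned = "second"`).
#' \eqn{\partial C/\partial u} equals the conditional CDF of \eqn{V} given
#' \eqn{U = u}; h-functions appear in the semi-competing risks likelihood
#' contributions of singly censored subjects and drive conditional sampling.
#'
#' @inheritParams copula_cdf
#' @param u,v evaluation points in \eqn{(0, 1]}.
#' @param conditioned which argument the derivative is taken with respect to.
#' @return numeric vector of values in \eqn{[0, 1]}.
#' @export
h_function <- function(family, u, v, theta,
                       conditioned = c("first", "second")) {
  family <- .check_family(family)
  conditioned <- match.arg(conditioned)
  .check_theta(family, theta)
  .check_uv(u, v, open = TRUE, upper_closed = TRUE)
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  theta <- rep_len(as.numeric(theta), n)
  wrt <- if (conditioned == "first") 1L else 2L
  ## dC/du at v = 1 is 1 (C(u, 1) = u); symmetric for the other side
  out <- numeric(n)
  atone <- if (wrt == 1L) v == 1 else u == 1
  out[atone] <- 1
  if (any(!atone))
    out[!atone] <- exp(.cop_loghfun(family, u[!atone], v[!atone],
                                    theta[!atone], wrt))
  pmin(out, 1)
}

#' Inverse conditional copula distribution
#'
#' Solves \eqn{h(v | u) = w} for \eqn{v}, i.e. inverts the conditional CDF
#' \eqn{\partial C/\partial u}.  Together with a uniform draw this yields
#' exact sampling from the copula by conditional inversion (Rosenblatt):
#' if \eqn{U \sim U(0,1)}, \eqn{W \sim U(0,1)} then \eqn{(U, inverse\_h(W, U))
#' \sim C_\theta}.  Closed forms are used for the Clayton, Frank and normal
#' families; Gumbel uses a safeguarded Newton iteration with a maintained
#' bisection bracket (absolute tolerance \eqn{10^{-10}}).
#'
#' @inheritParams copula_cdf
#' @param w target conditional probability in \eqn{(0, 1)}.
#' @param u conditioning value in \eqn{(0, 1)}.
#' @return numeric vector `v` with `h_function(family, u, v, theta) == w`.
#' @export
inverse_h <- function(family, w, u, theta) {
  family <- .check_family(family)
  .check_theta(family, theta)
  .check_uv(w, u, open = TRUE, upper_closed = FALSE)
  n <- max(length(w), length(u), length(theta))
  w <- rep_len(as.numeric(w), n); u <- rep_len(as.numeric(u), n)
  theta <- rep_len(as.numeric(theta), n)
  switch(family,
    clayton = {
      ## from w = u^{-(1+theta)} A^{-(1+theta)/theta}:
      ## v = (1 + u^{-theta} (w^{-theta/(1+theta)} - 1))^{-1/theta}
      tpow <- expm1(-theta / (1 + theta) * log(w))
      exp(-log1p(exp(-theta * log(u)) * tpow) / theta)
    },
    frank = {
      out <- w
      i <- abs(theta) >= FRANK_INDEP_EPS
      if (any(i)) {
        th <- theta[i]
        s <- -expm1(-th)
        a <- exp(-th * u[i]); gu <- -expm1(-th * u[i])
        gv <- w[i] * s / (a + w[i] * gu)
        out[i] <- -log1p(-gv) / th
      }
      out
    },
    gumbel = .gumbel_hinv(w, u, theta),
    normal = {
      rho <- pmin(pmax(theta, -NORMAL_RHO_MAX), NORMAL_RHO_MAX)
      stats::pnorm(stats::qnorm(w) * sqrt(1 - rho * rho) +
                     rho * stats::qnorm(u))
    }
  )
}

## Vectorized safeguarded Newton for the Gumbel inverse h-function.
## Works on v; the derivative of h(v|u) wrt v is the copula density.
.gumbel_hinv <- function(w, u, theta, tol = 1e-10, max_iter = 100L) {
  eps <- 1e-12
  lo <- rep(eps, length(w)); hi <- rep(1 - eps, length(w))
  logw <- log(w)
  v <- pmin(pmax(w, eps), 1 - eps) # independence-ish start
  for (it in seq_len(max_iter)) {
    lh <- .cop_loghfun("gumbel", u, v, theta, 1L)
    f <- lh - logw                      # solve log h = log w
    ## update bracket: h increasing in v
    lo <- ifelse(f < 0, v, lo)
    hi <- ifelse(f > 0, v, hi)
    if (all(abs(f) < tol) && all(hi - lo < tol)) break
    ## Newton step on log h: d log h / dv = c(u, v) / h(u, v)
    dlh <- exp(.cop_logdensity("gumbel", u, v, theta) - lh)
    step <- f / dlh
    vn <- v - step
    bad <- !is.finite(vn) | vn <= lo | vn >= hi
    vn[bad] <- (lo[bad] + hi[bad]) / 2
    if (all(abs(vn - v) < tol) && it > 3L) { v <- vn; break }
    v <- vn
  }
  if (any(!is.finite(v)))
    stop("inverse_h: Gumbel root search failed to converge (",
         sum(!is.finite(v)), " non-finite solutions)", call. = FALSE)
  v
}

#' Dependence-parameter link function
#'
#' Maps regression coefficients `b = (b0, b1, ..., bp)` and a covariate
#' vector (or matrix with one row per subject) to the copula dependence
#' parameter via the family-specific link that keeps \eqn{\theta} inside its
#' admissible range: Clayton \eqn{\theta = e^\eta}, Frank
#' \eqn{\theta = \eta}, Gumbel \eqn{\theta = e^\eta + 1} and normal
#' \eqn{\theta = \tanh(\eta) = (e^{2\eta} - 1)/(e^{2\eta} + 1)}, where
#' \eqn{\eta = b_0 + b_1 Z_1 + \dots + b_p Z_p}.
#'
#' @inheritParams copula_cdf
#' @param b numeric vector of length `p + 1` (intercept first).
#' @param z covariate vector of length `p`, or an `n x p` matrix.
#' @return numeric vector of dependence parameters, one per subject.
#' @export
link_theta <- function(family, b, z) {
  family <- .check_family(family)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  z <- as.matrix(z)
  if (length(b) != ncol(z) + 1)
    stop("length(b) must equal ncol(z) + 1", call. = FALSE)
  eta <- drop(cbind(1, z) %*% b)
  switch(family,
    clayton = exp(eta),
    frank   = eta,
    gumbel  = exp(eta) + 1,
    normal  = tanh(eta)
  )
}

#' Kendall's tau of a copula family
#'
#' Closed forms for Clayton (\eqn{\theta/(\theta+2)}), Gumbel
#' (\eqn{1 - 1/\theta}) and normal (\eqn{(2/\pi) \arcsin\theta}); the Frank
#' value \eqn{1 + 4(D_1(\theta) - 1)/\theta} uses numerical quadrature of the
#' Debye function \eqn{D_1}.
#'
#' @inheritParams copula_cdf
#' @return Kendall's tau in \eqn{[-1, 1]}.
#' @export
kendall_tau <- function(family, theta) {
  family <- .check_family(family)
  .check_theta(family, theta)
  switch(family,
    clayton = theta / (theta + 2),
    gumbel  = 1 - 1 / theta,
    normal  = (2 / pi) * asin(theta),
    frank   = vapply(theta, function(th) {
      if (abs(th) < FRANK_INDEP_EPS) return(0)
      d1 <- stats::integrate(function(t) t / expm1(t), 0, th)$value / th
      1 + 4 * (d1 - 1) / th
    }, numeric(1))
  )
}
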