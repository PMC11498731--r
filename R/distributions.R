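## Circular distributions and the zero-inflated gamma step kernel.
## No circular-statistics dependency is used: the wrapped Cauchy and von Mises
## densities, samplers and ML fits below are the package's own.

#' Wrap angles to (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the +pi representative so the interval is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Wrapped Cauchy density
#'
#' Circular density with mean direction `mu` and concentration `rho` in
#' \[0, 1): f(theta) = (1 - rho^2) / (2 pi (1 + rho^2 - 2 rho cos(theta - mu))).
#' `rho = 0` is the circular uniform; `rho -> 1` concentrates at `mu`.
#'
#' @param theta angle(s) in radians.
#' @param mu mean direction (radians).
#' @param rho concentration in \[0, 1).
#' @param log logical; return log density?
#' @return density (or log density) at `theta`.
#' @export
dwrpcauchy <- function(theta, mu = 0, rho = 0, log = FALSE) {
  if (any(rho < 0 | rho >= 1)) {
    stop("wrapped Cauchy concentration 'rho' must lie in [0, 1)")
  }
  ld <- log1p(-rho^2) - log(2 * pi) - log(1 + rho^2 - 2 * rho * cos(theta - mu))
  if (log) ld else exp(ld)
}

#' Sample from the wrapped Cauchy distribution
#'
#' Inversion sampler: theta = mu + 2 atan(((1-rho)/(1+rho)) tan(pi (u - 1/2))).
#'
#' @inheritParams dwrpcauchy
#' @param n number of draws.
#' @return `n` angles in (-pi, pi].
#' @export
rwrpcauchy <- function(n, mu = 0, rho = 0) {
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  u <- runif(n)
  wrap_angle(mu + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5))))
}

#' von Mises density
#'
#' f(theta) = exp(kappa cos(theta - mu)) / (2 pi I0(kappa)), evaluated with the
#' exponentially scaled Bessel function so large kappa stays finite.
#'
#' @param theta angle(s) in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration >= 0.
#' @param log logical; return log density?
#' @export
dvonmises <- function(theta, mu = 0, kappa = 0, log = FALSE) {
  if (any(kappa < 0)) stop("von Mises concentration 'kappa' must be >= 0")
  ld <- kappa * (cos(theta - mu) - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; falls back to the circular uniform
#' for kappa = 0.
#'
#' @inheritParams dvonmises
#' @param n number of draws.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(mu + out)
}

#' Maximum-likelihood von Mises fit
#'
#' Mean direction from the resultant vector; concentration solves
#' A1(kappa) = Rbar where A1 = I1/I0, by root finding on the scaled Bessel
#' ratio. Rbar ~ 0 returns kappa = 0 (circular uniform).
#'
#' @param theta angles in radians (NAs dropped).
#' @return list with `mu` and `kappa`.
#' @export
fit_vonmises <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) < 2) stop("need at least 2 angles to fit a von Mises")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  if (rbar < 1e-8) return(list(mu = mu, kappa = 0))
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (a1(700) < rbar) return(list(mu = mu, kappa = 700))
  kappa <- uniroot(function(k) a1(k) - rbar, c(1e-8, 700), tol = 1e-10)$root
  list(mu = mu, kappa = kappa)
}

#' Maximum-likelihood gamma fit
#'
#' Profile-likelihood fit: for fixed shape a the rate is a/mean(x), and the
#' profile score log(a) - digamma(a) - (log(mean(x)) - mean(log(x))) has a
#' unique root, found by bisection-safe `uniroot`.
#'
#' @param x positive values.
#' @return list with `shape` and `rate`.
#' @export
fit_gamma_mle <- function(x) {
  x <- x[is.finite(x)]
  if (any(x <= 0)) stop("gamma fit requires strictly positive values")
  if (length(x) < 2) stop("need at least 2 values")
  s <- log(mean(x)) - mean(log(x))
  if (s < 1e-12) stop("degenerate sample (zero log-dispersion)")
  f <- function(a) log(a) - digamma(a) - s
  # log(a) - digamma(a) decreases from +Inf to 0; bracket around the
  # Minka-style starting value
  a0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  lo <- a0 / 10; hi <- a0 * 10
  while (f(lo) < 0) lo <- lo / 10
  while (f(hi) > 0) hi <- hi * 10
  shape <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(shape = shape, rate = shape / mean(x))
}

#' Zero-inflated gamma log density for step lengths
#'
#' Mixture of a point mass `zeromass` at exactly s = 0 and
#' (1 - zeromass) * Gamma(shape, rate) for s > 0, parameterized by the step
#' mean and sd: shape = mu^2/sigma^2, rate = mu/sigma^2.
#'
#' @param s step length(s) in meters, >= 0.
#' @param mu mean step length (m) of the gamma component.
#' @param sigma sd (m) of the gamma component.
#' @param zeromass point-mass probability at s = 0, in \[0, 1).
#' @return log density at `s`.
#' @export
step_logdensity <- function(s, mu, sigma, zeromass = 0) {
  if (any(s < 0)) stop("step length must be >= 0")
  if (mu <= 0 || sigma <= 0) stop("'mu' and 'sigma' must be > 0")
  if (zeromass < 0 || zeromass >= 1) stop("'zeromass' must lie in [0, 1)")
  shape <- mu^2 / sigma^2
  rate <- mu / sigma^2
  ld <- log1p(-zeromass) + dgamma(s, shape = shape, rate = rate, log = TRUE)
  ld[s == 0] <- if (zeromass > 0) log(zeromass) else -Inf
  ld
}

#' Wrapped Cauchy log density for turning angles
#'
#' Thin wrapper with the argument names used by the movement model.
#'
#' @param theta turning angle(s) in (-pi, pi].
#' @param mu mean turning angle (radians).
#' @param rho concentration in \[0, 1).
#' @export
angle_logdensity <- function(theta, mu, rho) {
  dwrpcauchy(theta, mu = mu, rho = rho, log = TRUE)
}
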