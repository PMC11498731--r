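## Continuous-time correlated random walk for gap imputation.
## Model per coordinate: velocity is an Ornstein-Uhlenbeck process
##   dv = -beta v dt + sigma dW,
## position is its integral, observed with Gaussian error sd `obs_sd`.
## Discretized exactly over each inter-fix interval; fitted by Kalman-filter
## maximum likelihood; missing slots are filled with Kalman-smoother means.
## Units: beta in 1/h, sigma in m h^-3/2, positions in m, dt in hours.

#' CTCRW parameter container
#'
#' @param beta_vel velocity autocorrelation rate (1/h), > 0.
#' @param sigma_vel velocity noise scale (m h^-3/2), > 0.
#' @param obs_sd GPS error sd (m), >= 0.
#' @return list of class `ctcrw_params`.
#' @export
ctcrw_params <- function(beta_vel, sigma_vel, obs_sd = 0) {
  if (beta_vel <= 0 || sigma_vel <= 0 || obs_sd < 0) {
    stop("require beta_vel > 0, sigma_vel > 0, obs_sd >= 0")
  }
  structure(list(beta_vel = beta_vel, sigma_vel = sigma_vel,
                 obs_sd = obs_sd), class = "ctcrw_params")
}

## exact discretization of the integrated-OU model over dt hours
ctcrw_matrices <- function(beta, sigma, dt) {
  a <- exp(-beta * dt)
  Tm <- matrix(c(1, 0, (1 - a) / beta, a), 2, 2)
  qxx <- sigma^2 / beta^2 *
    (dt - 2 * (1 - a) / beta + (1 - a^2) / (2 * beta))
  qxv <- sigma^2 * (1 - a)^2 / (2 * beta^2)
  qvv <- sigma^2 * (1 - a^2) / (2 * beta)
  list(T = Tm, Q = matrix(c(qxx, qxv, qxv, qvv), 2, 2))
}

## prior variance for the first position of a burst (diffuse, fixed so the
## likelihood is a well-defined function of the parameters)
CTCRW_POS_PRIOR_VAR <- 1e7

## Kalman filter for one coordinate of one burst.
## y: observations at the regular lattice (NA = missing slot), dt hours.
## Returns loglik and, if smooth = TRUE, RTS-smoothed state means/vars.
ctcrw_filter <- function(y, dt, beta, sigma, obs_sd, smooth = FALSE) {
  n <- length(y)
  M <- ctcrw_matrices(beta, sigma, dt)
  Tm <- M$T; Q <- M$Q
  R <- obs_sd^2
  first <- which(!is.na(y))[1]
  m <- c(y[first], 0)
  P <- diag(c(CTCRW_POS_PRIOR_VAR, sigma^2 / (2 * beta)))
  ll <- 0
  mp <- matrix(NA_real_, n, 2); Pp <- array(NA_real_, c(2, 2, n))
  mf <- matrix(NA_real_, n, 2); Pf <- array(NA_real_, c(2, 2, n))
  for (t in seq_len(n)) {
    if (t > 1) {
      m <- Tm %*% m
      P <- Tm %*% P %*% t(Tm) + Q
    }
    mp[t, ] <- m; Pp[, , t] <- P
    if (!is.na(y[t])) {
      S <- P[1, 1] + R
      e <- y[t] - m[1]
      ll <- ll + dnorm(e, 0, sqrt(S), log = TRUE)
      K <- P[, 1] / S
      m <- m + K * e
      P <- P - outer(K, P[1, ])
      P <- (P + t(P)) / 2
    }
    mf[t, ] <- m; Pf[, , t] <- P
  }
  out <- list(loglik = ll)
  if (smooth) {
    ms <- mf; Ps <- Pf
    if (n > 1) {
      for (t in (n - 1):1) {
        G <- Pf[, , t] %*% t(Tm) %*% solve(Pp[, , t + 1])
        ms[t, ] <- mf[t, ] + G %*% (ms[t + 1, ] - mp[t + 1, ])
        Ps[, , t] <- Pf[, , t] +
          G %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(G)
      }
    }
    out$mean <- ms[, 1]
    out$var <- Ps[1, 1, ]
  }
  out
}

#' CTCRW log-likelihood of a regularized track
#'
#' Kalman-filter (prediction-error decomposition) log-likelihood of the
#' integrated Ornstein-Uhlenbeck model, summed over bursts and over the two
#' coordinates (treated as independent with shared parameters).
#'
#' @param track regularized `tm_track` (missing slots allowed).
#' @param params a `ctcrw_params`.
#' @return log-likelihood (scalar).
#' @export
ctcrw_loglik <- function(track, params) {
  dt <- (attr(track, "interval") %||% 3600) / 3600
  ll <- 0
  for (b in unique(track$burst)) {
    sub <- track[track$burst == b, , drop = FALSE]
    yx <- ifelse(sub$source == "observed", sub$x, NA_real_)
    yy <- ifelse(sub$source == "observed", sub$y, NA_real_)
    if (sum(!is.na(yx)) < 2) next
    ll <- ll +
      ctcrw_filter(yx, dt, params$beta_vel, params$sigma_vel,
                   params$obs_sd)$loglik +
      ctcrw_filter(yy, dt, params$beta_vel, params$sigma_vel,
                   params$obs_sd)$loglik
  }
  ll
}

#' Fit the CTCRW by maximum likelihood
#'
#' Quasi-Newton maximization over (log beta, log sigma\[, log obs_sd\]).
#'
#' @param track regularized `tm_track` with >= 10 observed fixes in some
#'   burst.
#' @param estimate_obs_sd logical; estimate the GPS error sd? If FALSE,
#'   `obs_sd` is held fixed.
#' @param obs_sd fixed GPS error sd (m) when `estimate_obs_sd = FALSE`.
#' @param start optional `ctcrw_params` starting values.
#' @return list of class `ctcrw_fit`: `params` (`ctcrw_params`), `loglik`,
#'   `convergence` (0 = ok), `counts`.
#' @export
fit_ctcrw <- function(track, estimate_obs_sd = TRUE, obs_sd = 30,
                      start = NULL) {
  nobs <- max(tapply(track$source == "observed", track$burst, sum))
  if (nobs < 10) stop("need >= 10 observed fixes in some burst")
  obs <- track[track$source == "observed", , drop = FALSE]
  if (is.null(start)) {
    disp <- sqrt(diff(obs$x)^2 + diff(obs$y)^2)
    s0 <- max(sd(disp), 1)
    start <- ctcrw_params(1, s0, if (estimate_obs_sd) obs_sd else
                          max(obs_sd, 1e-8))
  }
  nll <- function(p) {
    beta <- exp(p[1]); sigma <- exp(p[2])
    tau <- if (estimate_obs_sd) exp(p[3]) else obs_sd
    if (!is.finite(beta) || !is.finite(sigma) || beta > 1e4) return(1e10)
    # exploratory optimizer steps can visit extreme scales; their numeric
    # warnings are not informative
    ll <- suppressWarnings(
      ctcrw_loglik(track, list(beta_vel = beta, sigma_vel = sigma,
                               obs_sd = tau)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  p0 <- c(log(start$beta_vel), log(start$sigma_vel))
  if (estimate_obs_sd) p0 <- c(p0, log(max(start$obs_sd, 1)))
  opt <- optim(p0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("CTCRW fit did not converge (optim code ", opt$convergence,
         "): ", paste(opt$message, collapse = " "))
  }
  params <- ctcrw_params(exp(opt$par[1]), exp(opt$par[2]),
                         if (estimate_obs_sd) exp(opt$par[3]) else obs_sd)
  structure(list(params = params, loglik = -opt$value,
                 convergence = opt$convergence, counts = opt$counts),
            class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat(sprintf(
    "CTCRW fit: beta = %.4g /h, sigma = %.4g m h^-1.5, obs sd = %.4g m, logLik = %.2f\n",
    x$params$beta_vel, x$params$sigma_vel, x$params$obs_sd, x$loglik))
  invisible(x)
}

#' Impute missing fixes with Kalman-smoother means
#'
#' Observed fixes are never altered; missing slots inside bursts receive the
#' smoothed position mean and `source = "imputed"`.
#'
#' @param track regularized `tm_track`.
#' @param params a `ctcrw_params` (or a `ctcrw_fit`).
#' @return `tm_track` with no remaining missing slots.
#' @export
impute <- function(track, params) {
  if (inherits(params, "ctcrw_fit")) params <- params$params
  dt <- (attr(track, "interval") %||% 3600) / 3600
  out <- track
  for (b in unique(track$burst)) {
    sel <- which(track$burst == b)
    sub <- track[sel, , drop = FALSE]
    miss <- sub$source == "missing"
    if (!any(miss)) next
    yx <- ifelse(miss, NA_real_, sub$x)
    yy <- ifelse(miss, NA_real_, sub$y)
    sx <- ctcrw_filter(yx, dt, params$beta_vel, params$sigma_vel,
                       params$obs_sd, smooth = TRUE)
    sy <- ctcrw_filter(yy, dt, params$beta_vel, params$sigma_vel,
                       params$obs_sd, smooth = TRUE)
    out$x[sel[miss]] <- sx$mean[miss]
    out$y[sel[miss]] <- sy$mean[miss]
    out$source[sel[miss]] <- "imputed"
  }
  out
}

#' Simulate a CTCRW track on the hourly lattice
#'
#' Exact simulation of the discretized integrated-OU model, both
#' coordinates independent; used for parameter-recovery and imputation
#' checks.
#'
#' @param n number of fixes.
#' @param params a `ctcrw_params`.
#' @param x0,y0 starting position (m).
#' @param interval fix interval in seconds.
#' @param id animal id.
#' @param t0 first timestamp (POSIXct).
#' @return regularized `tm_track` (single burst, all observed).
#' @export
simulate_ctcrw <- function(n, params, x0 = 0, y0 = 0, interval = 3600,
                           id = "sim",
                           t0 = as.POSIXct("2020-01-01", tz = "UTC")) {
  dt <- interval / 3600
  M <- ctcrw_matrices(params$beta_vel, params$sigma_vel, dt)
  L <- t(chol(M$Q + diag(1e-12, 2)))
  sim_coord <- function(p0) {
    z <- matrix(NA_real_, n, 2)
    z[1, ] <- c(p0, rnorm(1, 0, params$sigma_vel /
                            sqrt(2 * params$beta_vel)))
    for (t in 2:n) {
      z[t, ] <- as.numeric(M$T %*% z[t - 1, ]) + as.numeric(L %*% rnorm(2))
    }
    z[, 1] + rnorm(n, 0, params$obs_sd)
  }
  tr <- new_track(data.frame(
    id = id, time = t0 + (seq_len(n) - 1) * interval,
    x = sim_coord(x0), y = sim_coord(y0),
    source = "observed", burst = 1L, stringsAsFactors = FALSE))
  attr(tr, "interval") <- interval
  tr
}
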