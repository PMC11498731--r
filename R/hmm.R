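## Two-state hidden Markov movement model: zero-inflated gamma step lengths,
## wrapped-Cauchy turning angles, logistic-link covariate-dependent
## transition probabilities, pooled likelihood across bursts/animals with a
## stationary initial distribution at each burst start. The forward and
## Viterbi recursions live in compiled code; everything here is the working
## scale plumbing, fitting, decoding and post-processing.

HMM_STATES <- c("encamping", "travelling")

#' Emission parameter container (2 states)
#'
#' @param mu,sigma gamma step mean and sd per state (m), > 0.
#' @param zeromass point-mass probability at step 0 per state, in \[0, 1).
#' @param angle_mean wrapped-Cauchy mean turning angle per state (rad).
#' @param angle_conc wrapped-Cauchy concentration per state, in \[0, 1).
#' @return list of class `emission_params`.
#' @export
emission_params <- function(mu, sigma, zeromass = c(0, 0),
                            angle_mean = c(0, 0), angle_conc = c(0, 0)) {
  stopifnot(length(mu) == 2, length(sigma) == 2)
  if (any(mu <= 0) || any(sigma <= 0)) stop("'mu' and 'sigma' must be > 0")
  if (any(zeromass < 0 | zeromass >= 1)) stop("'zeromass' must be in [0,1)")
  if (any(angle_conc < 0 | angle_conc >= 1)) {
    stop("'angle_conc' must be in [0,1)")
  }
  structure(list(mu = mu, sigma = sigma, zeromass = zeromass,
                 angle_mean = wrap_angle(angle_mean),
                 angle_conc = angle_conc), class = "emission_params")
}

#' Transition model container (2 states)
#'
#' Off-diagonal transition probabilities follow logistic regressions on
#' standardized covariates: gamma_12(z) = plogis(b12\[1\] + b12\[-1\] z) and
#' likewise gamma_21.
#'
#' @param beta12,beta21 coefficient vectors (intercept + one slope per
#'   covariate) for encamping->travelling and travelling->encamping.
#' @param covariates character vector of covariate names (may be empty).
#' @return list of class `transition_model`.
#' @export
transition_model <- function(beta12, beta21, covariates = character()) {
  if (length(beta12) != length(covariates) + 1 ||
      length(beta21) != length(covariates) + 1) {
    stop("each coefficient vector needs an intercept plus one slope per covariate")
  }
  structure(list(beta12 = beta12, beta21 = beta21, covariates = covariates),
            class = "transition_model")
}

#' Transition probability matrix at covariate values
#'
#' @param z named numeric vector (or 1-row data.frame) of standardized
#'   covariate values; ignored for an intercept-only model.
#' @param tmod a `transition_model`.
#' @return 2x2 matrix, rows (from-state) summing to 1.
#' @export
transition_matrix <- function(z, tmod) {
  zv <- if (length(tmod$covariates)) {
    as.numeric(as.data.frame(as.list(z))[1, tmod$covariates])
  } else numeric(0)
  g12 <- plogis(tmod$beta12[1] + sum(tmod$beta12[-1] * zv))
  g21 <- plogis(tmod$beta21[1] + sum(tmod$beta21[-1] * zv))
  matrix(c(1 - g12, g21, g12, 1 - g21), 2, 2,
         dimnames = list(HMM_STATES, HMM_STATES))
}

#' Stationary distribution of a 2-state chain
#'
#' delta solves delta G = delta: delta_1 = gamma_21 / (gamma_12 + gamma_21).
#'
#' @param G 2x2 transition matrix.
#' @return length-2 probability vector.
#' @export
stationary_dist <- function(G) {
  g12 <- G[1, 2]; g21 <- G[2, 1]
  s <- g12 + g21
  if (s <= 0 || !is.finite(s)) stop("gamma_12 + gamma_21 is numerically zero")
  c(g21 / s, g12 / s)
}

## per-step off-diagonal probabilities with the one-lag convention:
## the transition into step t uses the covariates of step t-1 (the step's
## start location); burst starts use their own row (value unused by the
## forward recursion, used for the stationary delta)
hmm_design <- function(steps, emission, tmod, delta = NULL) {
  T <- nrow(steps)
  ld <- cbind(
    step_logdensity(steps$step, emission$mu[1], emission$sigma[1],
                    emission$zeromass[1]),
    step_logdensity(steps$step, emission$mu[2], emission$sigma[2],
                    emission$zeromass[2]))
  ok <- is.finite(steps$angle)
  if (any(ok)) {
    ld[ok, 1] <- ld[ok, 1] +
      angle_logdensity(steps$angle[ok], emission$angle_mean[1],
                       emission$angle_conc[1])
    ld[ok, 2] <- ld[ok, 2] +
      angle_logdensity(steps$angle[ok], emission$angle_mean[2],
                       emission$angle_conc[2])
  }
  p <- length(tmod$covariates)
  if (p) {
    Z <- as.matrix(steps[, tmod$covariates, drop = FALSE])
    eta12_self <- tmod$beta12[1] + Z %*% tmod$beta12[-1]
    eta21_self <- tmod$beta21[1] + Z %*% tmod$beta21[-1]
  } else {
    eta12_self <- rep(tmod$beta12[1], T)
    eta21_self <- rep(tmod$beta21[1], T)
  }
  lag <- c(1, seq_len(T - 1))
  g12 <- plogis(eta12_self[lag])
  g21 <- plogis(eta21_self[lag])
  trans <- array(0, c(2, 2, T))
  trans[1, 1, ] <- 1 - g12; trans[1, 2, ] <- g12
  trans[2, 1, ] <- g21;     trans[2, 2, ] <- 1 - g21
  newburst <- if ("burst" %in% names(steps)) {
    c(TRUE, diff(as.integer(factor(paste(steps$id, steps$burst)))) != 0)
  } else c(TRUE, rep(FALSE, T - 1))
  if (is.null(delta)) {
    g12s <- plogis(eta12_self); g21s <- plogis(eta21_self)
    d1 <- g21s / (g12s + g21s)
    dmat <- cbind(d1, 1 - d1)
  } else {
    dmat <- matrix(rep(delta, each = T), T, 2)
  }
  list(ldens = ld, trans = trans, newburst = newburst, delta = dmat)
}

#' Forward log-likelihood of a step series
#'
#' Scaled forward recursion over all bursts (restarting at each burst with
#' the stationary distribution of the local transition matrix, or with an
#' explicit `delta`). Missing turning angles contribute only the
#' step-length term.
#'
#' @param steps `step_series` with columns `step`, `angle`, optional
#'   `id`/`burst`, and the (standardized) covariate columns named in `tmod`.
#' @param emission an `emission_params`.
#' @param tmod a `transition_model`.
#' @param delta optional explicit length-2 initial distribution.
#' @return log-likelihood (scalar).
#' @export
forward_loglik <- function(steps, emission, tmod, delta = NULL) {
  d <- hmm_design(steps, emission, tmod, delta)
  ll <- forward_loglik_cpp(d$ldens, as.numeric(d$trans), d$newburst, d$delta)
  if (!is.finite(ll)) {
    bad <- which(!is.finite(rowSums(d$ldens)))[1]
    stop("non-finite emission density at step ",
         if (is.na(bad)) "(underflow)" else bad)
  }
  ll
}

## ---- working-scale packing ---------------------------------------------

pack_hmm <- function(emission, tmod, zi) {
  c(log(emission$mu), log(emission$sigma),
    if (zi) qlogis(pmax(emission$zeromass, 1e-8)),
    emission$angle_mean, qlogis(pmax(emission$angle_conc, 1e-8)),
    tmod$beta12, tmod$beta21)
}

unpack_hmm <- function(par, p, zi) {
  i <- 0
  take <- function(n) { v <- par[i + seq_len(n)]; i <<- i + n; v }
  mu <- exp(take(2)); sigma <- exp(take(2))
  zm <- if (zi) plogis(take(2)) else c(0, 0)
  th <- wrap_angle(take(2)); rho <- plogis(take(2))
  b12 <- take(1 + p); b21 <- take(1 + p)
  list(emission = emission_params(mu, sigma, zm, th, rho),
       tmod = transition_model(b12, b21,
                               covariates = paste0("z", seq_len(p))))
}

hmm_par_names <- function(covariates, zi) {
  p <- length(covariates)
  cv <- c("(intercept)", covariates)
  c(paste0("log_mu_", 1:2), paste0("log_sigma_", 1:2),
    if (zi) paste0("logit_zeromass_", 1:2),
    paste0("angle_mean_", 1:2), paste0("logit_angle_conc_", 1:2),
    paste0("beta12_", cv), paste0("beta21_", cv))
}

#' Fit the two-state movement HMM
#'
#' Maximizes the pooled forward log-likelihood over the working scale
#' (log means/sds, logit zero-mass and concentration, unconstrained angle
#' means and transition coefficients) by quasi-Newton, optionally from
#' several jittered starts. Covariates are standardized internally (the
#' constants are stored on the fit). States are relabelled so state 1
#' ("encamping") has the smaller fitted step mean. Zero-mass parameters are
#' estimated only when the data contain exact zeros.
#'
#' @param steps `step_series` with `step`, `angle` and the covariate columns
#'   (natural scale).
#' @param covariates character vector of transition covariates (default
#'   distance-to-village, distance-to-water, NDVI).
#' @param inits list with mu, sigma, zeromass, angle_mean, angle_conc and
#'   optionally beta12/beta21 starting values; defaults are the standard
#'   short/long-step initial values (100/50, zero-mass 0.01, concentration
#'   0.3 vs 700/1000, 0.05, 0.7).
#' @param n_starts number of optimizer starts (first from `inits`, the rest
#'   jittered).
#' @param seed seed for the start jitter.
#' @return object of class `hmm_fit`.
#' @export
fit_hmm <- function(steps,
                    covariates = c("dist_village", "dist_water", "ndvi"),
                    inits = NULL, n_starts = 5, seed = 1) {
  covariates <- covariates[covariates %in% names(steps)]
  p <- length(covariates)
  keep <- is.finite(steps$step)
  if (p) keep <- keep & complete.cases(steps[, covariates, drop = FALSE])
  steps <- steps[keep, , drop = FALSE]
  if (nrow(steps) < 20) stop("too few usable steps to fit an HMM")
  std <- NULL
  if (p) {
    steps <- standardize_covariates(steps, covariates)
    std <- attr(steps, "standardization")
  }
  zi <- any(steps$step == 0)
  if (is.null(inits)) inits <- list()
  inits <- modifyList(list(mu = c(100, 700), sigma = c(50, 1000),
                           zeromass = c(0.01, 0.05), angle_mean = c(0, 0),
                           angle_conc = c(0.3, 0.7),
                           beta12 = c(qlogis(0.1), rep(0, p)),
                           beta21 = c(qlogis(0.1), rep(0, p))), inits)
  em0 <- emission_params(inits$mu, inits$sigma, inits$zeromass,
                         inits$angle_mean, inits$angle_conc)
  tm0 <- transition_model(inits$beta12, inits$beta21, covariates)
  # precomputed data views for the compiled likelihood
  sv <- steps$step
  av <- steps$angle
  ok <- is.finite(av)
  av[!ok] <- 0
  Z <- if (p) as.matrix(steps[, covariates, drop = FALSE]) else
    matrix(0, nrow(steps), 0)
  newburst <- if ("burst" %in% names(steps)) {
    c(TRUE, diff(as.integer(factor(paste(steps$id, steps$burst)))) != 0)
  } else c(TRUE, rep(FALSE, nrow(steps) - 1))
  nll <- function(par) {
    if (!all(is.finite(par)) || max(abs(par)) > 30) return(1e10)
    i <- 0L
    take <- function(n) { v <- par[i + seq_len(n)]; i <<- i + n; v }
    mu <- exp(take(2)); sigma <- exp(take(2))
    zm <- if (zi) plogis(take(2)) else c(0, 0)
    thet <- take(2); rho <- plogis(take(2))
    b12 <- take(1 + p); b21 <- take(1 + p)
    hmm_nll_cpp(sv, av, ok, Z, newburst, mu, sigma, zm, thet, rho, b12, b21)
  }
  p0 <- pack_hmm(em0, tm0, zi)
  starts <- list(p0)
  if (n_starts > 1) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- p0 + rnorm(length(p0), 0, 0.3)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, nll, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("HMM fit failed from every start")
  if (best$value >= 1e10) {
    stop("HMM fit did not reach a finite likelihood; optimizer trace: ",
         paste(utils::capture.output(str(best)), collapse = " "))
  }
  H <- stats::optimHess(best$par, nll)
  u <- unpack_hmm(best$par, p, zi)
  par <- best$par
  # label order: state 1 = smaller fitted step mean (encamping)
  if (u$emission$mu[1] > u$emission$mu[2]) {
    nb <- 1 + p
    blocks <- c(2, 2, if (zi) 2, 2, 2)
    idx <- integer(0); off <- 0
    for (bl in blocks) { idx <- c(idx, off + c(2, 1)); off <- off + bl }
    idx <- c(idx, off + nb + seq_len(nb), off + seq_len(nb))
    par <- par[idx]
    H <- H[idx, idx, drop = FALSE]
    u <- unpack_hmm(par, p, zi)
  }
  u$tmod$covariates <- covariates
  vcov_work <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-6, nrow(H)))
  })
  names(par) <- hmm_par_names(covariates, zi)
  dimnames(vcov_work) <- list(names(par), names(par))
  fit <- structure(list(
    emission = u$emission, tmod = u$tmod, zi = zi,
    covariates = covariates, standardization = std,
    loglik = -best$value, par_work = par, vcov_work = vcov_work,
    convergence = best$convergence, n_steps = nrow(steps),
    delta_mode = "stationary"), class = "hmm_fit")
  fit$table <- hmm_ci_table(fit)
  fit
}

## natural-scale point estimates with 95% working-scale CIs
hmm_ci_table <- function(fit) {
  par <- fit$par_work
  se <- sqrt(pmax(diag(fit$vcov_work), 0))
  lo <- par - qnorm(0.975) * se
  hi <- par + qnorm(0.975) * se
  nm <- names(par)
  trans <- function(v, nm) {
    out <- v
    out[grepl("^log_", nm)] <- exp(v[grepl("^log_", nm)])
    out[grepl("^logit_", nm)] <- plogis(v[grepl("^logit_", nm)])
    out
  }
  data.frame(parameter = sub("^(log_|logit_)", "", nm),
             estimate = trans(par, nm), lower = trans(lo, nm),
             upper = trans(hi, nm), row.names = NULL)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("2-state movement HMM (", x$n_steps, " steps), logLik = ",
      sprintf("%.2f", x$loglik), "\n", sep = "")
  for (k in 1:2) {
    cat(sprintf(
      " %-10s mu = %.1f m, sigma = %.1f m, zeromass = %.3f, angle mean = %.2f, conc = %.2f\n",
      HMM_STATES[k], x$emission$mu[k], x$emission$sigma[k],
      x$emission$zeromass[k], x$emission$angle_mean[k],
      x$emission$angle_conc[k]))
  }
  cat(" transition covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

## rebuild the design for a fitted model from natural-scale steps
prepare_fitted_design <- function(steps, fit) {
  if (length(fit$covariates)) {
    for (i in seq_along(fit$covariates)) {
      cv <- fit$covariates[i]
      j <- match(cv, fit$standardization$covariate)
      steps[[cv]] <- (steps[[cv]] - fit$standardization$mean[j]) /
        fit$standardization$sd[j]
    }
  }
  hmm_design(steps, fit$emission, fit$tmod)
}

#' Viterbi decoding
#'
#' Globally most probable joint state sequence under the fitted model, via
#' the max-product recursion with backtracking; ties break toward the lower
#' state index.
#'
#' @param steps `step_series` on the natural covariate scale (same schema
#'   as passed to [fit_hmm()]).
#' @param fit an `hmm_fit`.
#' @return factor of decoded states ("encamping"/"travelling").
#' @export
viterbi <- function(steps, fit) {
  d <- prepare_fitted_design(steps, fit)
  path <- viterbi_cpp(d$ldens, as.numeric(d$trans), d$newburst, d$delta)
  factor(HMM_STATES[path], levels = HMM_STATES)
}

#' Activity budget of a decoded state sequence
#'
#' @param states factor or character vector of states.
#' @return named proportions summing to 1.
#' @export
state_budget <- function(states) {
  if (!length(states)) stop("empty state sequence")
  tab <- table(factor(states, levels = HMM_STATES))
  prop <- as.numeric(tab) / length(states)
  names(prop) <- HMM_STATES
  prop
}

#' Stationary state probabilities along a covariate gradient
#'
#' Holds the other covariates at their (standardized) mean of 0, sweeps the
#' focal covariate over a natural-scale grid, and returns the stationary
#' encamping/travelling probabilities with delta-method 95% CIs (computed on
#' the logit scale from the working-scale covariance of the transition
#' coefficients).
#'
#' @param fit an `hmm_fit` with at least one transition covariate.
#' @param covariate focal covariate name.
#' @param grid natural-scale grid values (default: 50 points over +/- 2 sd).
#' @return data.frame: value, p_encamping, lower, upper, p_travelling.
#' @export
stationary_curve <- function(fit, covariate, grid = NULL) {
  j <- match(covariate, fit$covariates)
  if (is.na(j)) stop("'", covariate, "' is not a transition covariate")
  k <- match(covariate, fit$standardization$covariate)
  m <- fit$standardization$mean[k]; s <- fit$standardization$sd[k]
  if (is.null(grid)) grid <- seq(m - 2 * s, m + 2 * s, length.out = 50)
  zgrid <- (grid - m) / s
  p <- length(fit$covariates)
  bnames <- grep("^beta", names(fit$par_work))
  bpar <- fit$par_work[bnames]
  Vb <- fit$vcov_work[bnames, bnames, drop = FALSE]
  logit_d1 <- function(b, z) {
    b12 <- b[seq_len(1 + p)]; b21 <- b[1 + p + seq_len(1 + p)]
    zz <- rep(0, p); zz[j] <- z
    g12 <- plogis(b12[1] + sum(b12[-1] * zz))
    g21 <- plogis(b21[1] + sum(b21[-1] * zz))
    if (g12 + g21 <= 0) stop("gamma_12 + gamma_21 is numerically zero")
    qlogis(g21 / (g12 + g21))
  }
  out <- data.frame(value = grid, p_encamping = NA_real_, lower = NA_real_,
                    upper = NA_real_)
  for (i in seq_along(zgrid)) {
    f0 <- logit_d1(bpar, zgrid[i])
    gr <- vapply(seq_along(bpar), function(q) {
      h <- 1e-5 * max(1, abs(bpar[q]))
      bp <- bpar; bp[q] <- bp[q] + h
      (logit_d1(bp, zgrid[i]) - f0) / h
    }, 0)
    v <- max(as.numeric(t(gr) %*% Vb %*% gr), 0)
    out$p_encamping[i] <- plogis(f0)
    out$lower[i] <- plogis(f0 - qnorm(0.975) * sqrt(v))
    out$upper[i] <- plogis(f0 + qnorm(0.975) * sqrt(v))
  }
  out$p_travelling <- 1 - out$p_encamping
  out
}
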