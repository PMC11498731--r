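# Independent oracles used across the suite. Each recomputes a quantity by
# a route structurally different from the implementation: exhaustive
# enumeration, closed-form joint densities, quadrature or dense grid search.

# exhaustive forward likelihood: sum over all K^T state sequences.
# ld: T x K log emission densities; G: list of T K x K matrices where
# G[[t]] moves the chain from t-1 to t (G[[1]] unused); delta: initial dist.
enum_forward <- function(ld, G, delta) {
  T <- nrow(ld); K <- ncol(ld)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  tot <- 0
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    lp <- log(delta[s[1]]) + ld[1, s[1]]
    if (T > 1) {
      for (t in 2:T) lp <- lp + log(G[[t]][s[t - 1], s[t]]) + ld[t, s[t]]
    }
    tot <- tot + exp(lp)
  }
  log(tot)
}

# exhaustive Viterbi: argmax over all sequences (lexicographic-first on ties)
enum_viterbi <- function(ld, G, delta) {
  T <- nrow(ld); K <- ncol(ld)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    lp <- log(delta[s[1]]) + ld[1, s[1]]
    if (T > 1) {
      for (t in 2:T) lp <- lp + log(G[[t]][s[t - 1], s[t]]) + ld[t, s[t]]
    }
    if (lp > best) { best <- lp; arg <- s }
  }
  as.integer(unname(arg))
}

# emission log densities and lagged transition matrices for a single-burst
# step series, mirroring the model's documented conventions
oracle_design <- function(steps, emission, tmod) {
  T <- nrow(steps)
  ld <- matrix(0, T, 2)
  for (k in 1:2) {
    ld[, k] <- step_logdensity(steps$step, emission$mu[k],
                               emission$sigma[k], emission$zeromass[k])
    ok <- is.finite(steps$angle)
    ld[ok, k] <- ld[ok, k] +
      angle_logdensity(steps$angle[ok], emission$angle_mean[k],
                       emission$angle_conc[k])
  }
  G <- vector("list", T)
  for (t in seq_len(T)) {
    z <- if (length(tmod$covariates)) {
      tt <- max(t - 1, 1)
      setNames(as.numeric(steps[tt, tmod$covariates]), tmod$covariates)
    } else numeric(0)
    G[[t]] <- transition_matrix(z, tmod)
  }
  list(ld = ld, G = G)
}

# random 2-state parameter set on natural scales
random_hmm_pars <- function(p = 1) {
  list(
    emission = emission_params(
      mu = sort(runif(2, 50, 900)), sigma = runif(2, 30, 800),
      zeromass = runif(2, 0, 0.1), angle_mean = runif(2, -pi, pi),
      angle_conc = runif(2, 0, 0.9)),
    tmod = transition_model(
      beta12 = rnorm(1 + p, 0, 1), beta21 = rnorm(1 + p, 0, 1),
      covariates = paste0("c", seq_len(p))))
}

# random single-burst step series with the covariates named in `covs`
random_steps <- function(T, covs = "c1", zero_prob = 0.1) {
  df <- data.frame(
    id = "a", burst = 1L,
    step = ifelse(runif(T) < zero_prob, 0, rgamma(T, 2, 1 / 200)),
    angle = c(NA, wrap_angle(runif(T - 1, -pi, pi))))
  for (cv in covs) df[[cv]] <- rnorm(T)
  df
}

# joint multivariate-normal log density of the observed positions of one
# coordinate under the integrated-OU state-space model (prior at slot 1:
# mean (first obs, 0), var diag(1e7, sigma^2/(2 beta)))
ctcrw_joint_loglik <- function(y, dt, beta, sigma, obs_sd) {
  n <- length(y)
  a <- exp(-beta * dt)
  Tm <- matrix(c(1, 0, (1 - a) / beta, a), 2, 2)
  Q <- matrix(c(
    sigma^2 / beta^2 * (dt - 2 * (1 - a) / beta + (1 - a^2) / (2 * beta)),
    sigma^2 * (1 - a)^2 / (2 * beta^2),
    sigma^2 * (1 - a)^2 / (2 * beta^2),
    sigma^2 * (1 - a^2) / (2 * beta)), 2, 2)
  first <- which(!is.na(y))[1]
  m0 <- c(y[first], 0)
  V0 <- diag(c(1e7, sigma^2 / (2 * beta)))
  # state means and pairwise covariances by propagation
  means <- matrix(NA_real_, n, 2)
  means[1, ] <- m0
  Vt <- vector("list", n)
  Vt[[1]] <- V0
  for (t in 2:n) {
    means[t, ] <- as.numeric(Tm %*% means[t - 1, ])
    Vt[[t]] <- Tm %*% Vt[[t - 1]] %*% t(Tm) + Q
  }
  obs <- which(!is.na(y))
  k <- length(obs)
  S <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      s <- obs[min(i, j)]; t <- obs[max(i, j)]
      C <- Vt[[s]]
      if (t > s) for (u in (s + 1):t) C <- C %*% t(Tm)
      S[i, j] <- C[1, 1]
    }
  }
  S <- S + diag(obs_sd^2, k)
  mu <- means[obs, 1]
  e <- y[obs] - mu
  ch <- chol(S)
  -0.5 * k * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, e, transpose = TRUE)^2)
}

# exact two-sided Mann-Whitney p by enumeration, with U computed by pair
# counting (independent of the implementation's rank-sum route)
enum_mwu <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); N <- length(pooled)
  count_u <- function(idx) {
    x <- pooled[idx]; yv <- pooled[-idx]
    sum(outer(x, yv, ">")) + 0.5 * sum(outer(x, yv, "=="))
  }
  u_obs <- count_u(seq_len(na))
  mu <- na * (N - na) / 2
  sets <- utils::combn(N, na)
  us <- apply(sets, 2, count_u)
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# a tiny deterministic landscape stack for unit tests
toy_stack <- function(n = 60, seed = 99, cellsize = 100) {
  make_landscape(sim_config(seed = seed, nrow = n, ncol = n,
                            cellsize = cellsize))
}
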