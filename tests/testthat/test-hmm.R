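test_that("transition matrices are proper and respond to coefficients", {
  # zero coefficients give the maximally uncertain chain
  tm0 <- transition_model(c(0, 0), c(0, 0), "c1")
  expect_equal(as.vector(transition_matrix(c(c1 = 0), tm0)), rep(0.5, 4))
  # rows always sum to one
  set.seed(2)
  for (i in 1:10) {
    tm <- transition_model(rnorm(3), rnorm(3), c("c1", "c2"))
    G <- transition_matrix(c(c1 = rnorm(1), c2 = rnorm(1)), tm)
    expect_equal(rowSums(G), c(encamping = 1, travelling = 1))
    expect_true(all(G > 0 & G < 1))
  }
  # strongly negative intercepts pin the chain to its current state
  tmi <- transition_model(c(-10), c(-10), character())
  Gi <- transition_matrix(numeric(0), tmi)
  expect_lt(max(abs(diag(Gi) - 1)), 1e-4)
})

test_that("stationary distribution matches the left eigenvector", {
  set.seed(10)
  for (i in 1:25) {
    g12 <- runif(1); g21 <- runif(1)
    G <- matrix(c(1 - g12, g21, g12, 1 - g21), 2, 2)
    d <- stationary_dist(G)
    ev <- eigen(t(G))
    lead <- Re(ev$vectors[, which.max(Re(ev$values))])
    lead <- lead / sum(lead)
    expect_lt(max(abs(d - lead)), 1e-12)
    expect_equal(sum(d), 1)
  }
  # symmetric switching is a coin flip in the long run
  expect_equal(stationary_dist(matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)),
               c(0.5, 0.5))
})

test_that("forward likelihood matches exhaustive enumeration", {
  set.seed(14)
  for (rep in 1:6) {
    T <- sample(2:8, 1)
    pars <- random_hmm_pars(p = 1)
    steps <- random_steps(T)
    delta <- c(0.4, 0.6)
    ll <- forward_loglik(steps, pars$emission, pars$tmod, delta = delta)
    d <- oracle_design(steps, pars$emission, pars$tmod)
    expect_lt(abs(ll - enum_forward(d$ld, d$G, delta)), 1e-8)
  }
  # T = 1: log of the delta-weighted emission mixture
  steps1 <- random_steps(1)
  pars <- random_hmm_pars(p = 1)
  ll1 <- forward_loglik(steps1, pars$emission, pars$tmod, delta = c(0.3, 0.7))
  e1 <- exp(step_logdensity(steps1$step, pars$emission$mu[1],
                            pars$emission$sigma[1], pars$emission$zeromass[1]))
  e2 <- exp(step_logdensity(steps1$step, pars$emission$mu[2],
                            pars$emission$sigma[2], pars$emission$zeromass[2]))
  expect_equal(ll1, log(0.3 * e1 + 0.7 * e2))
})

test_that("forward likelihood is invariant to relabelling the states", {
  set.seed(15)
  pars <- random_hmm_pars(p = 1)
  steps <- random_steps(7)
  sw <- pars
  sw$emission <- emission_params(rev(pars$emission$mu),
                                 rev(pars$emission$sigma),
                                 rev(pars$emission$zeromass),
                                 rev(pars$emission$angle_mean),
                                 rev(pars$emission$angle_conc))
  sw$tmod <- transition_model(pars$tmod$beta21, pars$tmod$beta12, "c1")
  ll <- forward_loglik(steps, pars$emission, pars$tmod, delta = c(0.35, 0.65))
  llsw <- forward_loglik(steps, sw$emission, sw$tmod, delta = c(0.65, 0.35))
  expect_lt(abs(ll - llsw), 1e-10)
})

test_that("Viterbi equals the exhaustive argmax", {
  set.seed(16)
  for (rep in 1:6) {
    T <- sample(3:12, 1)
    pars <- random_hmm_pars(p = 1)
    steps <- random_steps(T)
    fit <- structure(list(emission = pars$emission, tmod = pars$tmod,
                          covariates = "c1",
                          standardization = data.frame(covariate = "c1",
                                                       mean = 0, sd = 1)),
                     class = "hmm_fit")
    path <- as.integer(viterbi(steps, fit))
    d <- oracle_design(steps, pars$emission, pars$tmod)
    delta <- stationary_dist(d$G[[1]])
    expect_equal(path, enum_viterbi(d$ld, d$G, delta))
  }
})

test_that("state budgets count proportions", {
  expect_equal(unname(state_budget(rep("travelling", 5))), c(0, 1))
  expect_equal(unname(state_budget(c("encamping", rep("travelling", 3)))),
               c(0.25, 0.75))
  set.seed(3)
  b <- state_budget(sample(c("encamping", "travelling"), 57, TRUE))
  expect_equal(sum(b), 1)
  expect_error(state_budget(character(0)), "empty")
})

test_that("fitting recovers a well-separated simulated model", {
  set.seed(77)
  sc <- sim_config(seed = 77, track_length = 1500)
  sc$hmm_truth$beta12 <- c(qlogis(0.15), 0.8, 0, 0)
  sc$hmm_truth$beta21 <- c(qlogis(0.07), -0.4, 0, 0)
  st <- toy_stack(80, seed = 77)
  sim <- simulate_hmm_track(sc, st, seed = 78)
  steps <- attach_covariates(compute_steps(sim$track), st, wrap = TRUE)
  fit <- fit_hmm(steps, covariates = "dist_village", n_starts = 1)
  expect_lt(abs(fit$emission$mu[1] - 100) / 100, 0.10)
  expect_lt(abs(fit$emission$mu[2] - 700) / 700, 0.10)
  # ascent: the optimum dominates the initial values
  em0 <- emission_params(c(100, 700), c(50, 1000), c(0.01, 0.05),
                         c(0, 0), c(0.3, 0.7))
  sstd <- steps
  sstd$dist_village <- (sstd$dist_village - fit$standardization$mean[1]) /
    fit$standardization$sd[1]
  ll0 <- forward_loglik(sstd, em0,
                        transition_model(c(qlogis(0.1), 0),
                                         c(qlogis(0.1), 0), "dist_village"))
  expect_gte(fit$loglik, ll0)
  # decoding matches the generating states almost everywhere
  acc <- mean(as.integer(viterbi(steps, fit)) == sim$states)
  expect_gt(acc, 0.9)
  # natural-scale CIs bracket their point estimates
  expect_true(all(fit$table$lower <= fit$table$estimate + 1e-9))
  expect_true(all(fit$table$upper >= fit$table$estimate - 1e-9))
})

test_that("the optimum is stable under perturbed starting values", {
  set.seed(88)
  sc <- sim_config(seed = 88, track_length = 800)
  st <- toy_stack(80, seed = 88)
  sim <- simulate_hmm_track(sc, st, seed = 89)
  steps <- attach_covariates(compute_steps(sim$track), st, wrap = TRUE)
  f1 <- fit_hmm(steps, covariates = "ndvi", n_starts = 1)
  pert <- list(mu = c(100, 700) * c(1.5, 0.5),
               sigma = c(50, 1000) * c(0.5, 1.5),
               zeromass = c(0.02, 0.03), angle_conc = c(0.5, 0.5))
  f2 <- fit_hmm(steps, covariates = "ndvi", inits = pert, n_starts = 1)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-4)
})

test_that("stationary curves obey the closed form and monotonicity", {
  # positive slope only into travelling: encamping probability falls
  tm <- transition_model(c(-1.5, 0.9), c(-2.2, 0), "c1")
  grid <- seq(-2, 2, length.out = 21)
  d1 <- vapply(grid, function(z) {
    stationary_dist(transition_matrix(c(c1 = z), tm))[1]
  }, 0)
  expect_true(all(diff(d1) < 0))
  expect_equal(d1, plogis(qlogis(d1)))  # proper probabilities
  # curve from a fitted object: probabilities sum to one across the grid
  set.seed(90)
  sc <- sim_config(seed = 90, track_length = 600)
  st <- toy_stack(70, seed = 90)
  sim <- simulate_hmm_track(sc, st, seed = 91)
  steps <- attach_covariates(compute_steps(sim$track), st, wrap = TRUE)
  fit <- fit_hmm(steps, covariates = "dist_village", n_starts = 1)
  cur <- stationary_curve(fit, "dist_village")
  expect_equal(cur$p_encamping + cur$p_travelling, rep(1, nrow(cur)))
  expect_true(all(cur$lower <= cur$p_encamping & cur$p_encamping <= cur$upper))
})
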