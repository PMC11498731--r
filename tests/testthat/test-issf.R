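sim_step_series <- function(n, seed = 1) {
  set.seed(seed)
  x <- cumsum(c(0, rgamma(n, 2, 0.005) * cos(runif(n, -pi, pi))))
  y <- cumsum(c(0, rgamma(n, 2, 0.005) * sin(runif(n, -pi, pi))))
  tr <- data.frame(id = "a",
                   time = as.POSIXct("2020-01-01", tz = "UTC") +
                     0:n * 3600,
                   x = x, y = y, source = "observed", burst = 1L)
  class(tr) <- c("tm_track", "data.frame")
  assign_diel(compute_steps(tr))
}

test_that("tentative kernel fit recovers gamma and von Mises parameters", {
  set.seed(61)
  steps <- data.frame(step = rgamma(10000, 2, 0.01),
                      angle = rvonmises(10000, 0.2, 1.5))
  k <- fit_kernel(steps)
  expect_lt(abs(k$shape - 2) / 2, 0.05)
  expect_lt(abs(k$rate - 0.01) / 0.01, 0.05)
  expect_lt(abs(k$kappa - 1.5) / 1.5, 0.1)
  # fitted gamma mean is shape/rate by construction
  expect_equal(k$shape / k$rate, mean(steps$step), tolerance = 0.02)
  # uniform turns give a vanishing concentration
  steps$angle <- wrap_angle(runif(10000, -pi, pi))
  expect_lt(fit_kernel(steps)$kappa, 0.1)
})

test_that("random candidate steps follow the kernel", {
  kern <- structure(list(shape = 2, rate = 0.01, mu = 0, kappa = 1),
                    class = "movement_kernel")
  set.seed(62)
  cand <- generate_random_steps(0, 0, prev_bearing = 0, kern, n = 1e5)
  expect_equal(nrow(cand), 1e5)
  # Monte Carlo mean within 1% of the gamma mean
  expect_lt(abs(mean(cand$step) - 200) / 200, 0.01)
  expect_equal(cand$x, cand$step * cos(cand$turn), tolerance = 1e-10)
  # a near-degenerate kernel collapses onto the straight-ahead projection
  tight <- structure(list(shape = 1e8, rate = 1e6, mu = 0, kappa = 1e6),
                     class = "movement_kernel")
  c2 <- generate_random_steps(10, 20, prev_bearing = pi / 4, tight, n = 50)
  expect_lt(max(abs(c2$x - (10 + 100 * cos(pi / 4)))), 1)
  expect_lt(max(abs(c2$y - (20 + 100 * sin(pi / 4)))), 1)
  expect_error(generate_random_steps(0, 0, NA, kern), "bearing")
})

test_that("strata have one used row and full candidate sets", {
  st <- toy_stack(60, seed = 63)
  steps <- sim_step_series(80, seed = 63)
  # keep the walk on the landscape
  steps[, c("x0", "y0", "x1", "y1")] <-
    lapply(steps[, c("x0", "y0", "x1", "y1")], function(v) {
      3000 + (v %% 2000)
    })
  kern <- fit_kernel(steps)
  strata <- build_strata(steps, st, kern, n_random = 15, seed = 7)
  per <- table(strata$stratum, strata$used)
  expect_true(all(per[, "1"] == 1))
  expect_true(all(per[, "0"] <= 15))
  # most strata keep the full 16 rows on an interior walk
  expect_gt(mean(rowSums(per) == 16), 0.8)
  # diel-specific forest dummies: reference class is non-forest
  expect_true(all(c("forest_day", "forest_night", "open_forest_day",
                    "open_forest_night") %in% names(strata)))
  expect_equal(strata$forest_day + strata$forest_night, strata$forest)
  # standardized continuous covariates
  expect_equal(mean(strata$ndvi), 0, tolerance = 1e-10)
  expect_equal(sd(strata$ndvi), 1, tolerance = 1e-10)
})

test_that("per-stratum seeding is order independent", {
  st <- toy_stack(60, seed = 64)
  steps <- sim_step_series(40, seed = 64)
  steps[, c("x0", "y0", "x1", "y1")] <-
    lapply(steps[, c("x0", "y0", "x1", "y1")], function(v) 3000 + (v %% 2000))
  kern <- fit_kernel(sim_step_series(200, seed = 65))
  s1 <- build_strata(steps, st, kern, seed = 11)
  s2 <- build_strata(steps, st, kern, seed = 11)
  expect_equal(s1$x, s2$x)
  expect_equal(s1$ndvi, s2$ndvi)
})

test_that("conditional logit matches its analytic anchors", {
  # beta = 0: every candidate equally likely, loglik = -N log(m)
  set.seed(66)
  n <- 40
  strata <- data.frame(
    stratum = rep(1:n, each = 16),
    used = rep(c(1L, rep(0L, 15)), n),
    z = rnorm(16 * n))
  f <- fit_clogit(strata, "z")
  # at beta = 0 every one of the 16 rows is equally likely
  expect_equal(clogit_loglik(strata, "z", 0), -n * log(16))
  # stratum-constant shifts cancel exactly from the likelihood
  strata2 <- strata
  strata2$z <- strata2$z + rep(rnorm(n, 0, 10), each = 16)
  f2 <- fit_clogit(strata2, "z")
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), unname(f2$coefficients),
               tolerance = 1e-6)
})

test_that("Newton-Raphson solution matches a dense grid search", {
  set.seed(67)
  strata <- data.frame(
    stratum = rep(1:3, each = 5),
    used = rep(c(1L, 0L, 0L, 0L, 0L), 3),
    z = rnorm(15))
  f <- fit_clogit(strata, "z")
  grid <- seq(-5, 5, by = 1e-3)
  X <- strata$z; sid <- strata$stratum; used <- strata$used == 1
  gll <- vapply(grid, function(b) {
    eta <- X * b
    sum(eta[used]) - sum(log(tapply(exp(eta), sid, sum)))
  }, 0)
  expect_lt(abs(f$loglik - max(gll)), 1e-6)
  expect_lt(abs(f$coefficients[["z"]] - grid[which.max(gll)]), 2e-3)
})

test_that("conditional logit agrees with survival::clogit", {
  skip_if_not_installed("survival")
  set.seed(68)
  n <- 120
  strata <- data.frame(
    stratum = rep(1:n, each = 8),
    used = rep(c(1L, rep(0L, 7)), n),
    a = rnorm(8 * n), b = rnorm(8 * n))
  # give selection some signal
  strata$a <- strata$a + 0.6 * strata$used
  f <- fit_clogit(strata, c("a", "b"))
  # one case per stratum: the Cox partial likelihood with Breslow ties is
  # exactly the conditional logistic likelihood
  strata$t1 <- 1
  ref <- survival::coxph(
    survival::Surv(t1, used) ~ a + b + survival::strata(stratum),
    data = strata, ties = "breslow")
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(f$table$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("separation is reported, not returned", {
  strata <- data.frame(
    stratum = rep(1:20, each = 4),
    used = rep(c(1L, 0L, 0L, 0L), 20))
  strata$z <- ifelse(strata$used == 1, 1, 0)  # perfect ranking
  expect_error(fit_clogit(strata, "z"), "separation")
})

test_that("model comparison orders by AIC with exact bookkeeping", {
  set.seed(69)
  n <- 60
  strata <- data.frame(
    stratum = rep(1:n, each = 8),
    used = rep(c(1L, rep(0L, 7)), n),
    a = rnorm(8 * n), b = rnorm(8 * n))
  strata$a <- strata$a + 0.5 * strata$used
  cmp <- compare_models(strata, list(m1 = "a", m2 = c("a", "b"),
                                     m2dup = c("a", "b")))
  expect_equal(cmp$table$aic,
               2 * cmp$table$k - 2 * cmp$table$loglik)
  # duplicated specification gives an identical AIC
  expect_equal(cmp$fits$m2$aic, cmp$fits$m2dup$aic)
  expect_equal(cmp$table$delta_aic[1], 0)
  expect_true(!is.unsorted(cmp$table$aic))
})

test_that("a pure-noise covariate worsens AIC on average", {
  set.seed(70)
  worse <- replicate(20, {
    n <- 40
    strata <- data.frame(
      stratum = rep(1:n, each = 8),
      used = rep(c(1L, rep(0L, 7)), n),
      a = rnorm(8 * n), noise = rnorm(8 * n))
    strata$a <- strata$a + 0.5 * strata$used
    f1 <- fit_clogit(strata, "a")
    f2 <- fit_clogit(strata, c("a", "noise"))
    # the noise term moves the log-likelihood by under half a chi-square
    expect_lt(2 * (f2$loglik - f1$loglik), qchisq(0.999, 1))
    f2$aic - f1$aic
  })
  expect_gt(mean(worse), 0)
})

test_that("relative selection strength follows the exponential contrast", {
  set.seed(72)
  n <- 150
  strata <- data.frame(
    stratum = rep(1:n, each = 8),
    used = rep(c(1L, rep(0L, 7)), n),
    ndvi = rnorm(8 * n))
  strata$ndvi <- strata$ndvi + 0.8 * strata$used
  f <- fit_clogit(strata, "ndvi")
  # identical compositions: RSS 1 with a zero-width interval
  r0 <- rss(f, c(ndvi = 0.7), c(ndvi = 0.7))
  expect_equal(r0$rss, 1)
  expect_equal(c(r0$lower, r0$upper), c(1, 1))
  # unit contrast reproduces exp(beta) exactly
  r1 <- rss(f, c(ndvi = 1), c(ndvi = 0))
  expect_equal(r1$rss, exp(f$coefficients[["ndvi"]]))
  # doubling the contrast squares the RSS
  r2 <- rss(f, c(ndvi = 2), c(ndvi = 0))
  expect_equal(r2$rss, r1$rss^2)
  # guards: unknown and movement terms are refused
  expect_error(rss(f, c(elev = 1), c(elev = 0)), "absent")
  expect_error(rss(f, c(log_step = 1), c(log_step = 0)), "movement")
})
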