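mk_track <- function(times_h, x, y, id = "t1") {
  tr <- data.frame(id = id,
                   time = as.POSIXct("2021-06-01", tz = "UTC") +
                     times_h * 3600,
                   x = x, y = y, source = "observed",
                   stringsAsFactors = FALSE)
  class(tr) <- c("tm_track", "data.frame")
  tr
}

test_that("regularization snaps, gap-fills and splits bursts", {
  # complete hourly track passes through unchanged
  tr <- mk_track(0:5, 1:6 * 10, rep(0, 6))
  reg <- regularize(tr)
  expect_equal(nrow(reg), 6)
  expect_true(all(reg$source == "observed"))
  # a 2-hour jump leaves one explicit missing slot
  tr2 <- mk_track(c(0, 2), c(0, 100), c(0, 0))
  reg2 <- regularize(tr2)
  expect_equal(nrow(reg2), 3)
  expect_equal(reg2$source, c("observed", "missing", "observed"))
  # a 30-hour gap with max_gap 24 h splits into two bursts, no fill
  tr3 <- mk_track(c(0, 1, 31, 32), rep(0, 4), rep(0, 4))
  reg3 <- regularize(tr3, max_gap = 24 * 3600)
  expect_equal(unique(reg3$burst), c(1L, 2L))
  expect_equal(nrow(reg3), 4)
  expect_true(all(reg3$source == "observed"))
  # duplicate slot keeps the earliest fix, with a warning
  tr4 <- mk_track(c(0, 1, 1.02, 2), c(0, 10, 99, 20), rep(0, 4))
  expect_warning(reg4 <- regularize(tr4), "earliest")
  expect_equal(reg4$x, c(0, 10, 20))
})

test_that("steps carry Euclidean lengths and signed wrapped turns", {
  tr <- mk_track(0:3, c(0, 3, 6, 3), c(0, 4, 8, 4))
  tr$burst <- 1L
  st <- compute_steps(tr)
  expect_equal(st$step, c(5, 5, 5))
  # colinear motion turns by zero; an exact reversal turns by pi
  expect_true(is.na(st$angle[1]))
  expect_equal(st$angle[2], 0)
  expect_equal(st$angle[3], pi)
})

test_that("step geometry is rigid-motion invariant", {
  set.seed(21)
  n <- 40
  tr <- mk_track(0:(n - 1), cumsum(rnorm(n, 0, 300)),
                 cumsum(rnorm(n, 0, 300)))
  tr$burst <- 1L
  st <- compute_steps(tr)
  # translation leaves lengths and turns unchanged
  tr2 <- tr; tr2$x <- tr$x + 5000; tr2$y <- tr$y - 1e4
  st2 <- compute_steps(tr2)
  expect_equal(st2$step, st$step)
  expect_equal(st2$angle, st$angle)
  # rotation leaves both unchanged too (turns are relative)
  th <- 0.83
  tr3 <- tr
  tr3$x <- cos(th) * tr$x - sin(th) * tr$y
  tr3$y <- sin(th) * tr$x + cos(th) * tr$y
  st3 <- compute_steps(tr3)
  expect_equal(st3$step, st$step)
  expect_equal(st3$angle, st$angle)
})

test_that("diel labels use the half-open local-day convention", {
  tr <- mk_track(c(12, 23, 6, 5.98) - 0.5, rep(0, 4), rep(0, 4))
  st <- data.frame(time = tr$time + 1800)  # step start on the hour
  st$step <- 1
  out <- assign_diel(st)
  expect_equal(out$diel, c("day", "night", "day", "night"))
})

test_that("displacement summaries give mean, SE and honest groups", {
  st <- data.frame(step = c(3, 4, 5, 7), g = c("a", "a", "a", "b"))
  tot <- displacement_summary(st)
  expect_equal(tot$mean, 4.75)
  byg <- displacement_summary(st, by = "g")
  expect_equal(byg$mean[byg$g == "a"], 4)
  expect_equal(byg$se[byg$g == "a"], sd(c(3, 4, 5)) / sqrt(3))
  # single observation: SE reported missing, not zero
  expect_true(is.na(byg$se[byg$g == "b"]))
  # constant grouping key reproduces the ungrouped summary
  st$k <- "all"
  byk <- displacement_summary(st, by = "k")
  expect_equal(byk$mean, tot$mean)
  expect_equal(byk$se, tot$se)
})

test_that("Mann-Whitney U obeys its identities", {
  # identical samples: central U, Z = 0
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), exact = FALSE)
  expect_equal(r$U_a, 4.5)
  expect_equal(r$Z, 0)
  # complete separation
  r2 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r2$U_a, 0)
  expect_equal(r2$U_b, 4)
  # U_a + U_b = n_a n_b under ties and random data
  set.seed(4)
  for (i in 1:20) {
    a <- sample(1:6, sample(2:12, 1), TRUE)
    b <- sample(1:6, sample(2:12, 1), TRUE)
    r3 <- mann_whitney_u(a, b, exact = FALSE)
    expect_equal(r3$U_a + r3$U_b, length(a) * length(b))
  }
  # everything tied: degenerate case
  r4 <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(r4$Z, 0)
  expect_equal(r4$p, 1)
})

test_that("exact Mann-Whitney matches full enumeration", {
  set.seed(9)
  for (i in 1:6) {
    a <- round(rnorm(sample(3:6, 1)), 1)
    b <- round(rnorm(sample(3:8, 1)), 1)
    mine <- mann_whitney_u(a, b)   # exact mode for min(n) <= 8
    orc <- enum_mwu(a, b)
    expect_equal(mine$U_a, orc$U)
    expect_equal(mine$p, orc$p)
  }
})

test_that("large-sample mode agrees with wilcox.test", {
  set.seed(12)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  mine <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(mine$U_a, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("track CSV round trip preserves fixes", {
  tr <- mk_track(0:3, c(0, 10.5, 20, 31), c(5, 4, 3, 2))
  p <- tempfile(fileext = ".csv")
  write_track_csv(tr, p)
  tr2 <- read_track_csv(p)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$time, tr$time)
  expect_equal(tr2$id, tr$id)
})
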