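test_that("built-up thresholding follows the >= rule", {
  r <- tm_raster(matrix(c(0.2, 0.8, 0.74, 0.75), 2, 2))
  v <- threshold_builtup(r, 0.75)
  expect_equal(as.vector(v$values), c(0, 1, 0, 1))
  # a cell exactly at the threshold is a settlement
  expect_equal(v$values[2, 2], 1)
  # nothing exceeds the threshold on an all-zero layer
  z <- threshold_builtup(tm_raster(matrix(0, 4, 4)), 0.75)
  expect_true(all(z$values == 0))
  expect_error(threshold_builtup(tm_raster(matrix(c(0.5, 1.2), 1, 2))),
               "\\[0, 1\\]")
})

test_that("distance transform equals the brute-force pairwise minimum", {
  set.seed(42)
  for (rep in 1:4) {
    n <- sample(10:50, 1)
    m <- matrix(0, n, n)
    m[sample(n * n, sample(1:12, 1))] <- 1
    r <- tm_raster(m, cellsize = 100)
    d <- euclidean_distance(r)
    src <- which(m == 1, arr.ind = TRUE)
    brute <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      brute[i, j] <- 100 * sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2))
    }
    expect_lt(max(abs(d$values - brute)), 1e-9)
    expect_true(all(d$values[m == 1] == 0))
  }
})

test_that("adding a source cell never increases any distance", {
  set.seed(7)
  m <- matrix(0, 30, 30)
  m[c(5, 400)] <- 1
  d1 <- euclidean_distance(tm_raster(m, cellsize = 50))
  m2 <- m; m2[600] <- 1
  d2 <- euclidean_distance(tm_raster(m2, cellsize = 50))
  expect_true(all(d2$values <= d1$values + 1e-12))
  expect_error(euclidean_distance(tm_raster(matrix(0, 5, 5))), "no source")
})

test_that("forest reclassification is total, correct and idempotent", {
  f6 <- tm_raster(matrix(1:6, 2, 3), categorical = TRUE)
  f3 <- reclassify_forest(f6)
  # dense and moderately dense merge into forest
  expect_equal(as.vector(f3$values)[1:2], c(1, 1))
  # open forest and shrubland merge into open forest
  expect_equal(as.vector(f3$values)[3:4], c(2, 2))
  # non-forest stays non-forest; water is neither forest class
  expect_equal(as.vector(f3$values)[5:6], c(3, 3))
  expect_setequal(unique(as.vector(f3$values)), 1:3)
  # idempotent on its own output
  expect_equal(reclassify_forest(f3)$values, f3$values)
  expect_error(reclassify_forest(tm_raster(matrix(7, 1, 1),
                                           categorical = TRUE)), "unknown")
})

test_that("stack resampling aligns grids without inventing categories", {
  set.seed(3)
  cont <- tm_raster(matrix(rnorm(400), 20, 20), cellsize = 100)
  cat6 <- tm_raster(matrix(sample(1:6, 400, TRUE), 20, 20), cellsize = 100,
                    categorical = TRUE)
  # identity resample leaves aligned layers untouched
  out <- resample_stack(list(a = cont, b = cat6), cellsize = 100)
  expect_equal(out$a$values, cont$values)
  # a constant layer stays constant under interpolation
  cst <- tm_raster(matrix(5, 40, 40), cellsize = 50)
  out2 <- resample_stack(list(a = cst), cellsize = 100)
  expect_true(all(abs(out2$a$values - 5) < 1e-12))
  # nearest-neighbour closure for categories on a finer source grid
  fine <- tm_raster(matrix(sample(c(1, 3, 5), 1600, TRUE), 40, 40),
                    cellsize = 50, categorical = TRUE)
  out3 <- resample_stack(list(f = fine), cellsize = 100)
  expect_true(all(out3$f$values %in% c(1, 3, 5)))
  far <- tm_raster(matrix(1, 5, 5), xll = 1e6, yll = 1e6, cellsize = 100)
  expect_error(resample_stack(list(a = cont, b = far)), "overlap")
})

test_that("covariate sampling is exact at cell centers and flags outsiders", {
  st <- toy_stack(60)
  cc <- cell_centers(st$ndvi)
  i <- 10; j <- 25
  cv <- sample_covariates(st, cc$x[j], cc$y[i])
  expect_equal(cv$ndvi, st$ndvi$values[i, j])
  expect_equal(cv$dist_village, st$dist_village$values[i, j])
  expect_equal(cv$forest3,
               c("forest", "open_forest", "non_forest")[st$forest3$values[i, j]])
  expect_false(cv$out_of_extent)
  # bilinear midpoint of two cells on a ramp is their mean
  ramp <- st
  ramp$ndvi <- tm_raster(matrix(rep(seq(0, 0.5, length.out = 60), each = 60),
                                60, 60), cellsize = 100)
  cvm <- sample_covariates(ramp, (cc$x[3] + cc$x[4]) / 2, cc$y[5])
  expect_equal(cvm$ndvi, mean(ramp$ndvi$values[5, 3:4]))
  # outside points flagged, not dropped
  out <- sample_covariates(st, c(cc$x[1], -500), c(cc$y[1], -500))
  expect_equal(out$out_of_extent, c(FALSE, TRUE))
  expect_equal(nrow(out), 2)
  # categorical samples stay in the closed 3-class set
  set.seed(8)
  pts <- sample_covariates(st, runif(200, 0, 6000), runif(200, 0, 6000))
  expect_true(all(pts$forest3 %in% c("forest", "open_forest", "non_forest")))
})

test_that("standardization is exact, reversible and guards constants", {
  df <- data.frame(a = c(1, 2, 3, 10), b = rnorm(4))
  z <- standardize_covariates(df, c("a", "b"))
  expect_equal(mean(z$a), 0)
  expect_equal(sd(z$a), 1)
  const <- attr(z, "standardization")
  expect_equal(unstandardize(z$a, "a", const), df$a)
  expect_error(standardize_covariates(data.frame(a = rep(2, 5)), "a"),
               "'a'")
})

test_that("ASCII grid round trip preserves grid and values", {
  set.seed(11)
  r <- tm_raster(matrix(rnorm(120), 10, 12), xll = 300, yll = -200,
                 cellsize = 50)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p)
  expect_equal(r2$values, r$values, tolerance = 1e-9)
  expect_equal(r2$xll, 300)
  expect_equal(r2$yll, -200)
  expect_equal(r2$cellsize, 50)
})
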