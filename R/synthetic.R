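## Seeded generators for landscapes and trajectories carrying the
## statistical structure the analysis assumes: smoothed-field NDVI,
## settlement patches, a rasterized river, NDVI-driven forest classes;
## state-switching movement with covariate-dependent transitions; and
## habitat-biased step selection. All randomness flows from the config's
## master seed through R's Mersenne-Twister generator.

#' Simulation configuration
#'
#' Defaults are the study conditions the rest of the package is tested
#' under: two movement states with short undirected steps
#' (mean 100 m, sd 50 m, zero-mass 0.01, wrapped-Cauchy concentration 0.3
#' around pi, i.e. turn-backs) versus long directed steps (mean 700 m,
#' sd 1000 m, zero-mass 0.05, concentration 0.7 around 0); switching
#' rates of 0.15 (encamping to travelling) and 0.07 (back), giving a
#' long-run budget near 32/68; transitions pushed toward travelling by
#' distance-to-village and NDVI and unaffected by water; and step
#' selection favouring high NDVI and large village distance.
#'
#' @param seed master seed.
#' @param nrow,ncol landscape size in cells (>= 50 each).
#' @param cellsize cell size in m (default 100).
#' @param n_villages number of settlement patches.
#' @param track_length steps per simulated track.
#' @param n_animals number of animals.
#' @param missing_rate probability a non-endpoint fix is dropped.
#' @param hmm_truth list: emission (`emission_params`), beta12, beta21,
#'   covariates.
#' @param issf_truth list: beta (named, standardized scale), kernel
#'   (`movement_kernel`), n_candidates.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, nrow = 100, ncol = 100, cellsize = 100,
                       n_villages = 3, track_length = 1000, n_animals = 5,
                       missing_rate = 0.1, hmm_truth = NULL,
                       issf_truth = NULL) {
  if (nrow < 50 || ncol < 50) stop("landscape must be at least 50 x 50 cells")
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stop("'missing_rate' must lie in [0, 0.5)")
  }
  if (is.null(hmm_truth)) {
    hmm_truth <- list(
      emission = emission_params(mu = c(100, 700), sigma = c(50, 1000),
                                 zeromass = c(0.01, 0.05),
                                 angle_mean = c(pi, 0),
                                 angle_conc = c(0.3, 0.7)),
      beta12 = c(qlogis(0.15), 0.8, 0, 0.4),
      beta21 = c(qlogis(0.07), -0.4, 0, -0.2),
      covariates = c("dist_village", "dist_water", "ndvi"))
  }
  if (is.null(issf_truth)) {
    issf_truth <- list(
      beta = c(ndvi = 1.0, dist_village = 0.5),
      kernel = structure(list(shape = 2, rate = 0.005, mu = 0, kappa = 0.5),
                         class = "movement_kernel"),
      n_candidates = 50)
  }
  structure(list(seed = seed, nrow = nrow, ncol = ncol, cellsize = cellsize,
                 n_villages = n_villages, track_length = track_length,
                 n_animals = n_animals, missing_rate = missing_rate,
                 hmm_truth = hmm_truth, issf_truth = issf_truth,
                 rng = "Mersenne-Twister"),
            class = "sim_config")
}

## separable Gaussian smoothing on a torus (consistent with wrapped
## covariate lookup)
smooth_field <- function(m, sd_cells = 3) {
  half <- ceiling(3 * sd_cells)
  k <- dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  sm_line <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -half:half, function(i, o) ((i + o - 1) %% n) + 1)
    as.numeric(matrix(v[idx], n) %*% k)
  }
  m <- apply(m, 2, sm_line)
  t(apply(m, 1, sm_line))
}

#' Generate a synthetic landscape stack
#'
#' NDVI is a smoothed Gaussian random field rescaled to \[-0.1, 0.6\];
#' settlements are dilated random patches in the built-up fraction layer
#' (thresholded at 0.75 into villages); water is a rasterized meandering
#' polyline; the 6-class forest layer follows NDVI thresholds with water
#' and settlement overrides. Distance layers and the 3-class forest merge
#' come from the landscape module.
#'
#' @param config a `sim_config`.
#' @return a `landscape_stack`.
#' @export
make_landscape <- function(config) {
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  ndvi <- smooth_field(matrix(rnorm(nr * nc), nr, nc), sd_cells = 3)
  ndvi <- -0.1 + 0.7 * (ndvi - min(ndvi)) / (max(ndvi) - min(ndvi))
  # settlements: random seed cells dilated to 3x3 patches
  built <- smooth_field(matrix(pmax(rnorm(nr * nc, 0.05, 0.05), 0), nr, nc),
                        sd_cells = 2)
  built <- pmin(pmax(built, 0), 0.4)
  vr <- sample(3:(nr - 2), config$n_villages, replace = TRUE)
  vc <- sample(3:(nc - 2), config$n_villages, replace = TRUE)
  for (v in seq_len(config$n_villages)) {
    built[vr[v] + (-1:1), vc[v] + (-1:1)] <- runif(9, 0.8, 1)
  }
  # water: one west-east meandering line
  water <- matrix(0, nr, nc)
  r <- sample(seq(nr %/% 4, 3 * nr %/% 4), 1)
  for (j in seq_len(nc)) {
    r <- min(max(r + sample(-1:1, 1), 1), nr)
    water[r, j] <- 1
  }
  # forest classes from NDVI; water and settlements override
  f6 <- matrix(5L, nr, nc)                      # non-forest
  f6[ndvi >= 0.05] <- 4L                        # shrub
  f6[ndvi >= 0.15] <- 3L                        # open
  f6[ndvi >= 0.25] <- 2L                        # moderately dense
  f6[ndvi >= 0.35] <- 1L                        # dense
  f6[built >= 0.75] <- 5L
  f6[water == 1] <- 6L
  cs <- config$cellsize
  mk <- function(v, categorical = FALSE, levels = NULL) {
    tm_raster(v, xll = 0, yll = 0, cellsize = cs, categorical = categorical,
              levels = levels)
  }
  landscape_stack(mk(ndvi), mk(built), mk(water, categorical = TRUE),
                  mk(f6, categorical = TRUE, levels = FOREST6_LEVELS))
}

#' Landscape-wide standardization constants
#'
#' Cell-level mean and sd of the continuous covariates; the scale on which
#' the generators evaluate transition and selection coefficients.
#'
#' @param stack a `landscape_stack`.
#' @return data.frame (covariate, mean, sd).
#' @export
landscape_constants <- function(stack) {
  lay <- list(ndvi = stack$ndvi, dist_village = stack$dist_village,
              dist_water = stack$dist_water)
  data.frame(
    covariate = names(lay),
    mean = vapply(lay, function(r) mean(r$values), 0),
    sd = vapply(lay, function(r) sd(as.numeric(r$values)), 0),
    row.names = NULL)
}

std_lookup <- function(stack, x, y, covariates, const, wrap) {
  cv <- sample_covariates(stack, x, y, wrap = wrap)
  z <- numeric(length(covariates))
  for (i in seq_along(covariates)) {
    j <- match(covariates[i], const$covariate)
    z[i] <- (cv[[covariates[i]]] - const$mean[j]) / const$sd[j]
  }
  z
}

#' Simulate a state-switching track over a landscape
#'
#' States evolve by the covariate-dependent transition matrix evaluated at
#' the walker's current location (landscape-standardized covariates); given
#' the state, the step comes from the zero-inflated gamma and the turn from
#' the wrapped Cauchy; the position advances by polar displacement. With
#' `boundary = "wrap"` covariates are looked up on the periodic tiling of
#' the landscape and positions are unbounded, so recorded steps follow the
#' generating distributions exactly; with `"reflect"` the walker bounces
#' off the landscape edge (reflections counted, and steps crossing the edge
#' are chord-shortened).
#'
#' @param config a `sim_config`.
#' @param stack a `landscape_stack` (from [make_landscape()]).
#' @param id animal id.
#' @param seed seed for this track (default the config master seed).
#' @param boundary "wrap" or "reflect".
#' @return list: `track` (`tm_track` of `track_length + 1` hourly fixes),
#'   `states` (true state per step), `n_reflected`.
#' @export
simulate_hmm_track <- function(config, stack, id = "sim1",
                               seed = config$seed,
                               boundary = c("wrap", "reflect")) {
  boundary <- match.arg(boundary)
  set.seed(seed)
  truth <- config$hmm_truth
  em <- truth$emission
  const <- landscape_constants(stack)
  ext <- raster_extent(stack$ndvi)
  wrap <- boundary == "wrap"
  # lean per-layer lookup state (bilinear, scalar, avoids data.frame
  # overhead in the hot loop)
  lay <- list(ndvi = stack$ndvi, dist_village = stack$dist_village,
              dist_water = stack$dist_water)[truth$covariates]
  cmean <- const$mean[match(truth$covariates, const$covariate)]
  csd <- const$sd[match(truth$covariates, const$covariate)]
  xmin <- ext[["xmin"]]; xmax <- ext[["xmax"]]
  ymin <- ext[["ymin"]]; ymax <- ext[["ymax"]]
  wx <- xmax - xmin; wy <- ymax - ymin
  nr <- nrow(stack$ndvi$values); nc <- ncol(stack$ndvi$values)
  cs <- stack$ndvi$cellsize
  bilin1 <- function(v, px, py) {
    col <- (px - xmin) / cs + 0.5
    row <- nr - ((py - ymin) / cs) + 0.5
    row <- min(max(row, 1), nr); col <- min(max(col, 1), nc)
    r0 <- min(max(floor(row), 1), max(nr - 1, 1))
    c0 <- min(max(floor(col), 1), max(nc - 1, 1))
    fr <- min(max(row - r0, 0), 1); fc <- min(max(col - c0, 0), 1)
    r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
    v[r0, c0] * (1 - fr) * (1 - fc) + v[r1, c0] * fr * (1 - fc) +
      v[r0, c1] * (1 - fr) * fc + v[r1, c1] * fr * fc
  }
  zstd <- function(px, py) {
    if (wrap) {
      px <- xmin + (px - xmin) %% wx
      py <- ymin + (py - ymin) %% wy
    }
    vapply(seq_along(lay), function(j) {
      (bilin1(lay[[j]]$values, px, py) - cmean[j]) / csd[j]
    }, 0)
  }
  b12 <- truth$beta12; b21 <- truth$beta21
  shape <- em$mu^2 / em$sigma^2
  rate <- shape / em$mu
  T <- config$track_length
  x <- numeric(T + 1); y <- numeric(T + 1)
  x[1] <- mean(c(xmin, xmax)); y[1] <- mean(c(ymin, ymax))
  states <- integer(T)
  z0 <- zstd(x[1], y[1])
  g12 <- plogis(b12[1] + sum(b12[-1] * z0))
  g21 <- plogis(b21[1] + sum(b21[-1] * z0))
  state <- if (runif(1) < g21 / (g12 + g21)) 1L else 2L
  bearing <- runif(1, -pi, pi)
  n_reflected <- 0L
  for (t in seq_len(T)) {
    z <- zstd(x[t], y[t])
    psw <- if (state == 1L) plogis(b12[1] + sum(b12[-1] * z)) else
      plogis(b21[1] + sum(b21[-1] * z))
    if (runif(1) < psw) state <- 3L - state
    states[t] <- state
    if (runif(1) < em$zeromass[state]) {
      s <- 0
    } else {
      s <- rgamma(1, shape = shape[state], rate = rate[state])
      bearing <- wrap_angle(bearing + rwrpcauchy(1, em$angle_mean[state],
                                                 em$angle_conc[state]))
    }
    nx <- x[t] + s * cos(bearing)
    ny <- y[t] + s * sin(bearing)
    if (boundary == "reflect") {
      refl <- function(v, lo, hi) {
        w <- hi - lo
        v <- (v - lo) %% (2 * w)
        lo + if (v > w) 2 * w - v else v
      }
      if (nx < xmin || nx > xmax || ny < ymin || ny > ymax) {
        n_reflected <- n_reflected + 1L
        nx2 <- refl(nx, xmin, xmax)
        ny2 <- refl(ny, ymin, ymax)
        bearing <- atan2(ny2 - y[t], nx2 - x[t])
        nx <- nx2; ny <- ny2
      }
    }
    x[t + 1] <- nx; y[t + 1] <- ny
  }
  tr <- new_track(data.frame(
    id = id,
    time = as.POSIXct("2020-01-01", tz = "UTC") + (0:T) * 3600,
    x = x, y = y, source = "observed", burst = 1L,
    stringsAsFactors = FALSE))
  attr(tr, "interval") <- 3600
  list(track = tr, states = states, n_reflected = n_reflected)
}

#' Simulate a habitat-selecting track
#'
#' Each step is drawn exactly from the continuous step-selection density
#' kernel(s, turn) * exp(beta' z(endpoint)) truncated to the landscape, by
#' rejection sampling: candidate steps are drawn from the true movement
#' kernel in batches of `n_candidates`, candidates outside the landscape
#' are rejected, and each remaining candidate is accepted with probability
#' exp(beta' z - eta_max), where eta_max bounds the habitat weight over the
#' landscape and z are landscape-standardized covariates at the candidate
#' endpoint. The first accepted candidate becomes the step.
#'
#' @param config a `sim_config`.
#' @param stack a `landscape_stack`.
#' @param id animal id.
#' @param seed seed for this track.
#' @return list: `track`, `n_rejected_batches` (batches with no accepted
#'   candidate).
#' @export
simulate_ssf_track <- function(config, stack, id = "sim1",
                               seed = config$seed) {
  set.seed(seed)
  truth <- config$issf_truth
  beta <- truth$beta
  kern <- truth$kernel
  C <- truth$n_candidates
  const <- landscape_constants(stack)
  ext <- raster_extent(stack$ndvi)
  covn <- names(beta)
  # cellwise bound on the habitat linear predictor; bilinear values are
  # convex combinations of cell values, so this bounds them too
  etacell <- 0
  for (v in covn) {
    j <- match(v, const$covariate)
    lay <- switch(v, ndvi = stack$ndvi, dist_village = stack$dist_village,
                  dist_water = stack$dist_water,
                  stop("unsupported selection covariate: ", v))
    etacell <- etacell + beta[[v]] * (lay$values - const$mean[j]) / const$sd[j]
  }
  etamax <- max(etacell)
  T <- config$track_length
  x <- numeric(T + 1); y <- numeric(T + 1)
  x[1] <- mean(ext[c("xmin", "xmax")]); y[1] <- mean(ext[c("ymin", "ymax")])
  bearing <- runif(1, -pi, pi)
  n_rejected_batches <- 0L
  for (t in seq_len(T)) {
    repeat {
      len <- rgamma(C, shape = kern$shape, rate = kern$rate)
      turn <- rvonmises(C, mu = kern$mu, kappa = kern$kappa)
      dir <- bearing + turn
      cx <- x[t] + len * cos(dir)
      cy <- y[t] + len * sin(dir)
      inside <- cx >= ext["xmin"] & cx <= ext["xmax"] &
        cy >= ext["ymin"] & cy <= ext["ymax"]
      acc <- rep(FALSE, C)
      if (any(inside)) {
        cv <- sample_covariates(stack, cx[inside], cy[inside])
        eta <- rep(0, sum(inside))
        for (v in covn) {
          j <- match(v, const$covariate)
          eta <- eta + beta[[v]] * (cv[[v]] - const$mean[j]) / const$sd[j]
        }
        acc[inside] <- runif(sum(inside)) < exp(eta - etamax)
      }
      if (any(acc)) break
      n_rejected_batches <- n_rejected_batches + 1L
    }
    pick <- which(acc)[1]
    x[t + 1] <- cx[pick]; y[t + 1] <- cy[pick]
    bearing <- dir[pick]
  }
  tr <- new_track(data.frame(
    id = id,
    time = as.POSIXct("2020-01-01", tz = "UTC") + (0:T) * 3600,
    x = x, y = y, source = "observed", burst = 1L,
    stringsAsFactors = FALSE))
  attr(tr, "interval") <- 3600
  list(track = tr, n_rejected_batches = n_rejected_batches)
}

#' Randomly drop fixes from a track
#'
#' Each non-endpoint fix is dropped independently with probability `rate`;
#' the first and last fix are always retained. The result is a raw
#' (irregular) track suitable for [regularize()].
#'
#' @param track a `tm_track`.
#' @param rate drop probability in \[0, 0.5).
#' @param seed seed.
#' @return `tm_track` with rows removed.
#' @export
inject_missingness <- function(track, rate, seed = 1) {
  if (rate < 0 || rate >= 0.5) stop("'rate' must lie in [0, 0.5)")
  if (rate == 0) return(track)
  set.seed(seed)
  n <- nrow(track)
  drop <- runif(n) < rate
  drop[c(1, n)] <- FALSE
  out <- track[!drop, , drop = FALSE]
  attr(out, "interval") <- attr(track, "interval")
  out
}

#' Attach landscape covariates to a step series
#'
#' Samples the stack at each step's endpoint and binds the covariate
#' columns (NDVI, distances, forest classes).
#'
#' @param steps a `step_series`.
#' @param stack a `landscape_stack`.
#' @param wrap periodic lookup (for wrap-simulated tracks).
#' @return `steps` with covariate columns appended.
#' @export
attach_covariates <- function(steps, stack, wrap = FALSE) {
  cv <- sample_covariates(stack, steps$x1, steps$y1, wrap = wrap)
  cbind(steps, cv)
}
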