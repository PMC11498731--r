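## Covariate-stack preparation: built-up thresholding, exact Euclidean
## distance transforms, forest-class merging, alignment, sampling and
## standardization. The stack feeds both the transition model of the HMM and
## the step-selection strata.

FOREST6_LEVELS <- c("dense", "moderately_dense", "open", "shrub",
                    "non_forest", "water")
FOREST3_LEVELS <- c("forest", "open_forest", "non_forest")

#' Assemble a landscape covariate stack
#'
#' All layers must share one grid. Derived layers (`dist_village`,
#' `dist_water`, `forest3`) are computed on construction: villages are the
#' built-up fraction thresholded at `builtup_threshold`, distances are exact
#' Euclidean cell-center distances, and the 6-class forest scheme is merged
#' to 3 classes ({dense, moderately_dense} -> forest; {open, shrub} ->
#' open_forest; {non_forest, water} -> non_forest).
#'
#' @param ndvi `tm_raster`, values in \[-1, 1\].
#' @param builtup_fraction `tm_raster`, proportion built-up in \[0, 1\].
#' @param water_mask binary `tm_raster` (1 = water).
#' @param forest6 categorical `tm_raster` coded 1..6 over
#'   dense, moderately_dense, open, shrub, non_forest, water.
#' @param builtup_threshold proportion at/above which a cell is a settlement.
#' @return object of class `landscape_stack` with layers `ndvi`,
#'   `builtup_fraction`, `water_mask`, `forest6`, `village_mask`,
#'   `dist_village`, `dist_water`, `forest3`.
#' @export
landscape_stack <- function(ndvi, builtup_fraction, water_mask, forest6,
                            builtup_threshold = 0.75) {
  layers <- list(ndvi = ndvi, builtup_fraction = builtup_fraction,
                 water_mask = water_mask, forest6 = forest6)
  for (nm in names(layers)[-1]) {
    if (!same_grid(layers[[1]], layers[[nm]])) {
      a <- layers[[1]]; b <- layers[[nm]]
      stop(sprintf(
        "grid mismatch: 'ndvi' is %dx%d @%gm origin (%g,%g) but '%s' is %dx%d @%gm origin (%g,%g)",
        nrow(a$values), ncol(a$values), a$cellsize, a$xll, a$yll, nm,
        nrow(b$values), ncol(b$values), b$cellsize, b$xll, b$yll))
    }
  }
  if (any(ndvi$values < -1 | ndvi$values > 1, na.rm = TRUE)) {
    stop("invalid layer: NDVI outside [-1, 1]")
  }
  village_mask <- threshold_builtup(builtup_fraction, builtup_threshold)
  stack <- structure(
    list(ndvi = ndvi,
         builtup_fraction = builtup_fraction,
         water_mask = water_mask,
         forest6 = forest6,
         village_mask = village_mask,
         dist_village = euclidean_distance(village_mask),
         dist_water = euclidean_distance(water_mask),
         forest3 = reclassify_forest(forest6),
         builtup_threshold = builtup_threshold),
    class = "landscape_stack")
  stack
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("landscape_stack: %d x %d cells at %g m\n",
              nrow(x$ndvi$values), ncol(x$ndvi$values), x$ndvi$cellsize))
  cat(" layers:", paste(setdiff(names(x), "builtup_threshold"),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Threshold a built-up fraction layer into a settlement mask
#'
#' A cell is a village/settlement cell iff its built-up fraction is greater
#' than or equal to the threshold (default 0.75).
#'
#' @param builtup_fraction `tm_raster` with values in \[0, 1\].
#' @param threshold proportion in \[0, 1\].
#' @return binary `tm_raster` (1 = settlement).
#' @export
threshold_builtup <- function(builtup_fraction, threshold = 0.75) {
  v <- builtup_fraction$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("invalid layer: built-up fraction outside [0, 1]")
  }
  tm_raster((!is.na(v) & v >= threshold) * 1,
            xll = builtup_fraction$xll, yll = builtup_fraction$yll,
            cellsize = builtup_fraction$cellsize, categorical = TRUE)
}

## exact 1D lower-envelope squared distance transform (Felzenszwalb &
## Huttenlocher); f is squared distance in cell units, Inf = no source
edt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a binary raster
#'
#' Each cell receives the minimum cell-center to cell-center Euclidean
#' distance (in meters) to any source cell (value 1). Exact separable
#' two-pass transform; source cells map to 0.
#'
#' @param mask binary `tm_raster`; cells equal to 1 are sources.
#' @return continuous `tm_raster` of distances in meters.
#' @export
euclidean_distance <- function(mask) {
  src <- mask$values == 1
  src[is.na(src)] <- FALSE
  if (!any(src)) stop("distance transform undefined: no source cells")
  # large finite stand-in for +Inf keeps the envelope arithmetic exact
  # (true squared distances never exceed nrow^2 + ncol^2 cells)
  f <- ifelse(src, 0, 1e12)
  nr <- nrow(f); nc <- ncol(f)
  # pass 1: along columns (vertical), pass 2: along rows
  for (j in seq_len(nc)) f[, j] <- if (nr > 1) edt_1d(f[, j]) else f[, j]
  for (i in seq_len(nr)) f[i, ] <- if (nc > 1) edt_1d(f[i, ]) else f[i, ]
  tm_raster(sqrt(f) * mask$cellsize, xll = mask$xll, yll = mask$yll,
            cellsize = mask$cellsize, categorical = FALSE)
}

#' Merge the 6-class forest scheme into 3 classes
#'
#' dense + moderately dense -> forest; open + shrub -> open forest;
#' non-forest and water -> non-forest. The mapping is total over the 6-class
#' codes and idempotent on its own output codes.
#'
#' @param forest6 categorical `tm_raster` coded 1..6 (see
#'   [landscape_stack()]), or already 3-class coded 1..3.
#' @return categorical `tm_raster` coded 1 = forest, 2 = open_forest,
#'   3 = non_forest, with `levels` set.
#' @export
reclassify_forest <- function(forest6) {
  v <- forest6$values
  codes <- sort(unique(as.vector(v[!is.na(v)])))
  if (identical(forest6$levels, FOREST3_LEVELS)) {
    if (!all(codes %in% 1:3)) stop("unknown forest category code(s): ",
                                   paste(setdiff(codes, 1:3), collapse = ", "))
    return(forest6)
  }
  if (!all(codes %in% 1:6)) {
    stop("unknown forest category code(s): ",
         paste(setdiff(codes, 1:6), collapse = ", "))
  }
  map <- c(1, 1, 2, 2, 3, 3)  # dense, mdense -> forest; open, shrub ->
                              # open_forest; non_forest, water -> non_forest
  out <- v
  out[!is.na(v)] <- map[v[!is.na(v)]]
  tm_raster(out, xll = forest6$xll, yll = forest6$yll,
            cellsize = forest6$cellsize, categorical = TRUE,
            levels = FOREST3_LEVELS)
}

#' Resample a covariate stack onto a shared grid
#'
#' All layers are resampled onto one grid at the target cell size covering
#' the intersection of the layer extents: continuous layers bilinearly,
#' categorical layers nearest-neighbour. Layers already on the target grid
#' pass through unchanged.
#'
#' @param layers named list of `tm_raster` (roles as in [landscape_stack()]).
#' @param cellsize target cell size in meters (default 100).
#' @return named list of aligned `tm_raster` objects.
#' @export
resample_stack <- function(layers, cellsize = 100) {
  exts <- lapply(layers, raster_extent)
  xmin <- max(vapply(exts, `[[`, 0, "xmin"))
  xmax <- min(vapply(exts, `[[`, 0, "xmax"))
  ymin <- max(vapply(exts, `[[`, 0, "ymin"))
  ymax <- min(vapply(exts, `[[`, 0, "ymax"))
  if (xmax - xmin < cellsize || ymax - ymin < cellsize) {
    stop("layer extents do not overlap by at least one target cell")
  }
  nc <- floor((xmax - xmin) / cellsize)
  nr <- floor((ymax - ymin) / cellsize)
  target <- list(xll = xmin, yll = ymin, cellsize = cellsize,
                 nrow = nr, ncol = nc)
  lapply(layers, function(r) {
    if (abs(r$cellsize - cellsize) < 1e-9 && abs(r$xll - xmin) < 1e-9 &&
        abs(r$yll - ymin) < 1e-9 && nrow(r$values) == nr &&
        ncol(r$values) == nc) r else resample_raster(r, target)
  })
}

#' Sample the covariate stack at planar points
#'
#' Continuous layers (NDVI, distances) are sampled bilinearly, the 3-class
#' forest layer nearest-neighbour and expanded to one-hot columns with
#' non-forest as the reference. Out-of-extent points are flagged, not
#' dropped.
#'
#' @param stack a `landscape_stack`.
#' @param x,y point coordinates (m).
#' @param wrap logical; if TRUE, coordinates are wrapped onto the stack
#'   extent (periodic tiling) before sampling, so no point is out of extent.
#' @return data.frame with columns `ndvi`, `dist_village`, `dist_water`,
#'   `forest3` (character), `forest`, `open_forest` (one-hot),
#'   `out_of_extent` (logical).
#' @export
sample_covariates <- function(stack, x, y, wrap = FALSE) {
  ext <- raster_extent(stack$ndvi)
  if (wrap) {
    x <- ext["xmin"] + (x - ext["xmin"]) %% (ext["xmax"] - ext["xmin"])
    y <- ext["ymin"] + (y - ext["ymin"]) %% (ext["ymax"] - ext["ymin"])
  }
  oob <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  f3 <- sample_raster(stack$forest3, x, y, method = "nearest")
  f3chr <- rep(NA_character_, length(x))
  ok <- !is.na(f3)
  f3chr[ok] <- FOREST3_LEVELS[f3[ok]]
  data.frame(
    ndvi = sample_raster(stack$ndvi, x, y),
    dist_village = sample_raster(stack$dist_village, x, y),
    dist_water = sample_raster(stack$dist_water, x, y),
    forest3 = f3chr,
    forest = as.numeric(f3chr == "forest"),
    open_forest = as.numeric(f3chr == "open_forest"),
    out_of_extent = unname(oob)
  )
}

#' Standardize covariate columns
#'
#' Centers and scales each named column to mean 0, sd 1 over the rows
#' provided, and stores the constants so coefficients can be mapped back to
#' natural units.
#'
#' @param df data.frame.
#' @param cols character vector of column names to standardize.
#' @return `df` with the columns replaced by z-scores; attribute
#'   `standardization` is a data.frame (covariate, mean, sd).
#' @export
standardize_covariates <- function(df, cols) {
  const <- data.frame(covariate = cols, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(cols)) {
    v <- df[[cols[i]]]
    m <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize constant covariate '", cols[i], "' (sd = 0)")
    }
    df[[cols[i]]] <- (v - m) / s
    const$mean[i] <- m; const$sd[i] <- s
  }
  attr(df, "standardization") <- const
  df
}

#' Invert a standardization
#'
#' @param z standardized values.
#' @param covariate covariate name.
#' @param constants the `standardization` attribute from
#'   [standardize_covariates()].
#' @return values on the natural scale.
#' @export
unstandardize <- function(z, covariate, constants) {
  i <- match(covariate, constants$covariate)
  if (is.na(i)) stop("no standardization constants for '", covariate, "'")
  z * constants$sd[i] + constants$mean[i]
}

#' Read a landscape stack from an ASCII-grid role map
#'
#' The YAML config maps layer roles to file paths, e.g.
#' `ndvi: layers/ndvi.asc`. Required roles: ndvi, builtup_fraction,
#' water_mask, forest6. Optional key `builtup_threshold` (default 0.75).
#'
#' @param config_path path to the YAML role map.
#' @param cellsize target cell size for alignment (default 100 m).
#' @return a `landscape_stack`.
#' @export
read_landscape <- function(config_path, cellsize = 100) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  need <- c("ndvi", "builtup_fraction", "water_mask", "forest6")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("landscape config missing roles: ",
                         paste(miss, collapse = ", "))
  pth <- function(p) if (file.exists(p)) p else file.path(base, p)
  layers <- list(
    ndvi = read_ascii_grid(pth(cfg$ndvi)),
    builtup_fraction = read_ascii_grid(pth(cfg$builtup_fraction)),
    water_mask = read_ascii_grid(pth(cfg$water_mask), categorical = TRUE),
    forest6 = read_ascii_grid(pth(cfg$forest6), categorical = TRUE,
                              levels = FOREST6_LEVELS)
  )
  aligned <- resample_stack(layers, cellsize = cellsize)
  landscape_stack(aligned$ndvi, aligned$builtup_fraction, aligned$water_mask,
                  aligned$forest6,
                  builtup_threshold = cfg$builtup_threshold %||% 0.75)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
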