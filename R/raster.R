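## Minimal planar raster container. Coordinates are projected meters; the grid
## is row 1 = northernmost row (ASCII-grid convention), values stored as a
## matrix. Cell registration: cell (r, c) has its center at
##   x = xll + (c - 1/2) * cellsize
##   y = yll + (nrow - r + 1/2) * cellsize

#' Create a planar raster
#'
#' @param values numeric matrix; row 1 is the top (northern) row.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in meters.
#' @param categorical logical; treat values as category codes (sampled and
#'   resampled nearest-neighbour)?
#' @param levels optional character vector naming the categories; codes are
#'   indices into `levels`.
#' @return an object of class `tm_raster`.
#' @export
tm_raster <- function(values, xll = 0, yll = 0, cellsize = 100,
                      categorical = FALSE, levels = NULL) {
  values <- as.matrix(values)
  if (cellsize <= 0) stop("'cellsize' must be > 0")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         categorical = categorical, levels = levels),
    class = "tm_raster"
  )
}

#' @export
print.tm_raster <- function(x, ...) {
  cat(sprintf("tm_raster: %d x %d cells, %g m, origin (%g, %g)%s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              if (x$categorical) " [categorical]" else ""))
  invisible(x)
}

#' @export
dim.tm_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

same_grid <- function(a, b, tol = 1e-6) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell-center coordinates of a raster
#'
#' @param r a `tm_raster`.
#' @return list with vectors `x` (per column) and `y` (per row, top first).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, top row
#' first.
#'
#' @param path file path.
#' @param categorical logical; mark the layer categorical?
#' @param levels optional category names (see [tm_raster()]).
#' @return a `tm_raster`.
#' @export
read_ascii_grid <- function(path, categorical = FALSE, levels = NULL) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid ", path, ": expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  tm_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
            cellsize = hdr$cellsize, categorical = categorical,
            levels = levels)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `tm_raster`.
#' @param path output file path.
#' @param digits significant digits for continuous layers.
#' @export
write_ascii_grid <- function(r, path, digits = 10) {
  m <- r$values
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"
  ), con)
  fmt <- if (r$categorical) "%d" else paste0("%.", digits, "g")
  apply(m, 1, function(row) {
    writeLines(paste(sprintf(fmt, row), collapse = " "), con)
  })
  invisible(path)
}

## fractional (row, col) position of points on the raster's cell-center grid;
## used by both bilinear sampling and resampling
point_rowcol <- function(r, x, y) {
  col <- (x - r$xll) / r$cellsize + 0.5
  row <- nrow(r$values) - ((y - r$yll) / r$cellsize) + 0.5
  list(row = row, col = col)
}

#' Sample one raster at planar points
#'
#' Continuous layers are interpolated bilinearly between cell centers
#' (clamped to the edge half-cell so sampling is exact at all cell centers);
#' categorical layers take the nearest cell. Points outside the raster extent
#' return NA.
#'
#' @param r a `tm_raster`.
#' @param x,y point coordinates in meters.
#' @param method "auto" (bilinear for continuous, nearest for categorical),
#'   "bilinear" or "nearest".
#' @return numeric vector of sampled values (NA out of extent).
#' @export
sample_raster <- function(r, x, y, method = c("auto", "bilinear", "nearest")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (r$categorical) "nearest" else "bilinear"
  ext <- raster_extent(r)
  inside <- x >= ext["xmin"] & x <= ext["xmax"] &
    y >= ext["ymin"] & y <= ext["ymax"]
  out <- rep(NA_real_, length(x))
  if (!any(inside)) return(out)
  rc <- point_rowcol(r, x[inside], y[inside])
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (method == "nearest") {
    ri <- pmin(pmax(round(rc$row), 1L), nr)
    ci <- pmin(pmax(round(rc$col), 1L), nc)
    out[inside] <- r$values[cbind(ri, ci)]
    return(out)
  }
  row <- pmin(pmax(rc$row, 1), nr)
  col <- pmin(pmax(rc$col, 1), nc)
  r0 <- pmin(pmax(floor(row), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1L), nc - 1L)
  if (nr == 1L) r0 <- rep(1L, length(row))
  if (nc == 1L) c0 <- rep(1L, length(col))
  fr <- pmin(pmax(row - r0, 0), 1)
  fc <- pmin(pmax(col - c0, 0), 1)
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  v <- r$values
  out[inside] <-
    v[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    v[cbind(r1, c0)] * fr * (1 - fc) +
    v[cbind(r0, c1)] * (1 - fr) * fc +
    v[cbind(r1, c1)] * fr * fc
  out
}

#' Resample a raster onto a target grid
#'
#' @param r source `tm_raster`.
#' @param target `tm_raster` (or list with xll, yll, cellsize, nrow, ncol)
#'   defining the output grid.
#' @return a `tm_raster` on the target grid.
#' @export
resample_raster <- function(r, target) {
  if (inherits(target, "tm_raster")) {
    nr <- nrow(target$values); nc <- ncol(target$values)
    xll <- target$xll; yll <- target$yll; cs <- target$cellsize
  } else {
    nr <- target$nrow; nc <- target$ncol
    xll <- target$xll; yll <- target$yll; cs <- target$cellsize
  }
  xs <- xll + (seq_len(nc) - 0.5) * cs
  ys <- yll + (nr - seq_len(nr) + 0.5) * cs
  pts <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  vals <- sample_raster(r, xs[pts$col], ys[pts$row])
  m <- matrix(NA_real_, nr, nc)
  m[cbind(pts$row, pts$col)] <- vals
  tm_raster(m, xll = xll, yll = yll, cellsize = cs,
            categorical = r$categorical, levels = r$levels)
}
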