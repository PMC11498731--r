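## Track regularization, step geometry, diel labelling, displacement
## summaries and the day/night rank-sum comparison. A track is a data.frame
## (class tm_track) with columns id, time (POSIXct), x, y, source
## ("observed"/"imputed"/"missing"), burst.

new_track <- function(df) {
  class(df) <- c("tm_track", "data.frame")
  df
}

#' Read a track CSV
#'
#' Expected columns: `id`, `timestamp` (ISO-8601, parsed to UTC), `x`, `y`
#' in projected meters; optional `source`.
#'
#' @param path CSV file path.
#' @return a `tm_track` data.frame (id, time, x, y, source).
#' @export
read_track_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("track CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  tm <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(tm)) stop("unparseable timestamp(s) in ", path)
  new_track(data.frame(id = as.character(df$id), time = tm,
                       x = as.numeric(df$x), y = as.numeric(df$y),
                       source = if ("source" %in% names(df)) df$source
                                else "observed",
                       stringsAsFactors = FALSE))
}

#' Write a track CSV
#'
#' @param track a `tm_track`.
#' @param path output path.
#' @export
write_track_csv <- function(track, path) {
  out <- data.frame(id = track$id,
                    timestamp = format(track$time, "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"),
                    x = track$x, y = track$y, source = track$source)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regularize a track onto the hourly lattice
#'
#' Fixes are snapped to the nearest slot of a lattice with the nominal
#' interval, anchored at the first fix's nearest whole interval. Fixes
#' farther than `tolerance` from any slot are dropped (counted); duplicate
#' slots keep the earliest fix with a warning. Runs of empty slots no longer
#' than `max_gap` become explicit missing rows (to be imputed); longer gaps
#' split the track into bursts.
#'
#' @param track a `tm_track` (one animal).
#' @param interval nominal fix interval in seconds (default 3600).
#' @param max_gap longest gap, in seconds, bridged inside one burst
#'   (default 24 h); longer gaps start a new burst.
#' @param tolerance snapping tolerance in seconds (default 300 = 5 min).
#' @return `tm_track` with columns id, time, x, y, source
#'   ("observed"/"missing"), burst; attribute `dropped` counts off-lattice
#'   fixes.
#' @export
regularize <- function(track, interval = 3600, max_gap = 24 * 3600,
                       tolerance = 300) {
  if (nrow(track) < 2) stop("need at least 2 fixes to regularize")
  if (length(unique(track$id)) > 1) {
    stop("regularize() works on one animal at a time")
  }
  track <- track[order(track$time), , drop = FALSE]
  t0 <- as.numeric(track$time)
  anchor <- round(t0[1] / interval) * interval
  slot <- round((t0 - anchor) / interval)
  offset <- t0 - (anchor + slot * interval)
  keep <- abs(offset) <= tolerance
  dropped <- sum(!keep)
  track <- track[keep, , drop = FALSE]
  slot <- slot[keep]
  if (anyDuplicated(slot)) {
    warning("duplicate fixes in the same slot; keeping the earliest")
    first <- !duplicated(slot)
    track <- track[first, , drop = FALSE]
    slot <- slot[first]
  }
  if (nrow(track) < 2) stop("fewer than 2 fixes remain after snapping")
  # burst splitting on gaps > max_gap
  gap <- c(0, diff(slot)) * interval
  burst <- cumsum(gap > max_gap) + 1L
  out <- list()
  for (b in unique(burst)) {
    sl <- slot[burst == b]
    sub <- track[burst == b, , drop = FALSE]
    full <- seq(sl[1], sl[length(sl)])
    i <- match(full, sl)
    out[[b]] <- data.frame(
      id = sub$id[1],
      time = as.POSIXct(anchor + full * interval, tz = "UTC",
                        origin = "1970-01-01"),
      x = sub$x[i], y = sub$y[i],
      source = ifelse(is.na(i), "missing", "observed"),
      burst = b, stringsAsFactors = FALSE)
  }
  res <- new_track(do.call(rbind, out))
  attr(res, "interval") <- interval
  attr(res, "dropped") <- dropped
  res
}

#' Compute step lengths and turning angles
#'
#' Step t is the displacement from fix t to fix t+1 within a burst:
#' `step` is the Euclidean length (m) and `angle` the signed turn
#' (counterclockwise positive, wrapped to (-pi, pi]) relative to the
#' previous step's bearing. Angles are NA on the first step of a burst and
#' wherever an adjacent step has zero length. Bursts with fewer than 2 fixes
#' are skipped with a warning.
#'
#' @param track a regularized (and typically imputed) `tm_track`.
#' @return data.frame of class `step_series`: id, burst, time (step start),
#'   x0, y0, x1, y1 (endpoints), step, angle, bearing, imputed (either
#'   endpoint imputed).
#' @export
compute_steps <- function(track) {
  if (!"burst" %in% names(track)) track$burst <- 1L
  res <- list()
  for (b in unique(track$burst)) {
    sub <- track[track$burst == b, , drop = FALSE]
    sub <- sub[sub$source != "missing", , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) {
      warning("burst ", b, " has fewer than 2 fixes; skipped")
      next
    }
    dx <- diff(sub$x); dy <- diff(sub$y)
    s <- sqrt(dx^2 + dy^2)
    bearing <- atan2(dy, dx)
    ang <- c(NA_real_, wrap_angle(diff(bearing)))
    # turns adjacent to a zero-length step are geometrically undefined
    zero <- s == 0
    ang[c(FALSE, zero[-length(zero)])] <- NA_real_
    ang[zero] <- NA_real_
    res[[length(res) + 1]] <- data.frame(
      id = sub$id[1], burst = b, time = sub$time[-n],
      x0 = sub$x[-n], y0 = sub$y[-n], x1 = sub$x[-1], y1 = sub$y[-1],
      step = s, angle = ang, bearing = bearing,
      imputed = sub$source[-n] == "imputed" | sub$source[-1] == "imputed",
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no burst with at least 2 fixes")
  out <- do.call(rbind, res)
  class(out) <- c("step_series", "data.frame")
  out
}

#' Label steps day or night
#'
#' A step is "day" iff its starting local clock hour lies in
#' \[day_start, day_end); otherwise "night".
#'
#' @param steps a `step_series`.
#' @param day_start,day_end local clock hours bounding daytime
#'   (defaults 6 and 18).
#' @param tz time zone used to read the clock hour (default "UTC"; pass the
#'   study's local zone if timestamps are stored in UTC).
#' @return `steps` with a `diel` column ("day"/"night").
#' @export
assign_diel <- function(steps, day_start = 6, day_end = 18, tz = "UTC") {
  lt <- as.POSIXlt(steps$time, tz = tz)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  steps$diel <- ifelse(hour >= day_start & hour < day_end, "day", "night")
  steps
}

#' Displacement summary: mean and standard error of step length by group
#'
#' @param steps a `step_series` (needs `step`; grouping columns as named).
#' @param by character vector of grouping columns (e.g. c("diel",
#'   "forest3")); NULL summarizes everything in one row.
#' @return data.frame with group columns plus n, mean, se (se is NA for
#'   single-step groups). Empty groups are absent rather than zero rows.
#' @export
displacement_summary <- function(steps, by = NULL) {
  f <- function(v) {
    c(n = length(v), mean = mean(v),
      se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }
  if (is.null(by)) {
    st <- f(steps$step)
    return(data.frame(n = st["n"], mean = st["mean"], se = st["se"],
                      row.names = NULL))
  }
  miss <- setdiff(by, names(steps))
  if (length(miss)) stop("grouping column(s) not found: ",
                         paste(miss, collapse = ", "))
  keep <- complete.cases(steps[, by, drop = FALSE])
  agg <- aggregate(steps$step[keep], steps[keep, by, drop = FALSE], f)
  out <- cbind(agg[, by, drop = FALSE], as.data.frame(agg$x))
  out[order(do.call(paste, out[, by, drop = FALSE])), , drop = FALSE]
}

#' Mann-Whitney U rank-sum test
#'
#' U by rank summation with midranks for ties; two-sided p-value from the
#' tie-corrected normal approximation with continuity correction, or, when
#' `exact = TRUE` (default for min(n) <= 8), from full enumeration of all
#' choose(n_a + n_b, n_a) group labelings of the pooled sample (ties
#' handled exactly). If every pooled value is tied, Z = 0 and p = 1.
#'
#' @param a,b numeric samples.
#' @param exact logical or NULL; NULL picks exact when min(length(a),
#'   length(b)) <= 8.
#' @return list with `U_a`, `U_b`, `Z`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- min(na, nb) <= 8
  pooled <- c(a, b)
  r <- rank(pooled)
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  N <- na + nb
  mu <- na * nb / 2
  ties <- table(pooled)
  tiecor <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((N + 1) - tiecor / (N * (N - 1)))
  if (v <= 0) {
    return(list(U_a = Ua, U_b = Ub, Z = 0, p = 1, method = "degenerate"))
  }
  cc <- ifelse(abs(Ua - mu) > 0.5, 0.5, 0)   # continuity correction
  Z <- (Ua - mu - sign(Ua - mu) * cc) / sqrt(v)
  if (exact) {
    idx <- utils::combn(N, na)
    rs <- colSums(matrix(r[idx], nrow = na))
    Uperm <- rs - na * (na + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(Ua - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- 2 * pnorm(-abs(Z))
    method <- "normal approximation"
  }
  list(U_a = Ua, U_b = Ub, Z = Z, p = min(p, 1), method = method)
}
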