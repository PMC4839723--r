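#' A luminance profile perpendicular to growth banding
#'
#' A 1-D record of image brightness against distance measured perpendicular
#' to growth banding. Grayscale runs 0 (dark) to 255 (bright); dark loci
#' are band boundaries. The `residual` column (brightness minus a smooth
#' trend) exists only after [detrend_profile()].
#'
#' @param distance_um strictly increasing distances, micrometres.
#' @param brightness grayscale values.
#' @param residual optional detrended brightness.
#' @return A data.frame classed `luminance_profile`.
#' @export
luminance_profile <- function(distance_um, brightness, residual = NULL) {
  stopifnot(length(distance_um) == length(brightness))
  if (any(diff(distance_um) <= 0)) {
    stop("distance grid must be strictly increasing")
  }
  df <- data.frame(distance_um = as.numeric(distance_um),
                   brightness = as.numeric(brightness))
  if (!is.null(residual)) {
    stopifnot(length(residual) == nrow(df))
    df$residual <- as.numeric(residual)
  }
  class(df) <- c("luminance_profile", "data.frame")
  df
}

#' Extract a luminance profile from a banded grayscale raster
#'
#' Averages one-pixel-wide lines parallel to the banding to suppress local
#' luminescence variation, stepping the line perpendicular to the banding
#' to build the profile. The band angle is measured in the image plane
#' from the column (vertical) axis, so `band_angle_in_image = 0` with
#' vertical bands reduces to plain column means.
#'
#' @param raster numeric matrix (rows x cols) of grayscale values 0-255.
#' @param band_angle_in_image angle of the band lines from the image
#'   column axis, degrees.
#' @param line_length_px length of each averaged line, pixels.
#' @param px_per_um image scale (default 9 px/um).
#' @param step_px perpendicular step between profile points, pixels.
#' @return A [luminance_profile()]; points whose averaging line left the
#'   raster are flagged in the logical attribute `shortened`.
#' @export
profile_from_image <- function(raster, band_angle_in_image = 0,
                               line_length_px = 1000, px_per_um = 9,
                               step_px = 1) {
  if (!is.matrix(raster) || !is.numeric(raster)) {
    stop("raster must be a numeric matrix (single channel)")
  }
  if (!length(raster)) stop("empty raster")
  nr <- nrow(raster); nc <- ncol(raster)
  th <- band_angle_in_image * pi / 180
  # t_hat: along-band direction (x = col, y = row); n_hat: perpendicular.
  t_hat <- c(sin(th), cos(th))
  n_hat <- c(cos(th), -sin(th))
  ctr <- c((nc + 1) / 2, (nr + 1) / 2)
  half_diag <- sqrt(nr^2 + nc^2) / 2
  d_seq <- seq(-half_diag, half_diag, by = step_px)
  s_seq <- seq(-(line_length_px - 1) / 2, (line_length_px - 1) / 2, by = 1)

  bilinear <- function(x, y) {
    # NA outside the raster
    x0 <- floor(x); y0 <- floor(y)
    ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nc & y0 + 1 <= nr
    v <- rep(NA_real_, length(x))
    if (any(ok)) {
      fx <- x[ok] - x0[ok]; fy <- y[ok] - y0[ok]
      i0 <- y0[ok]; j0 <- x0[ok]
      v[ok] <- raster[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
        raster[cbind(i0, j0 + 1)] * fx * (1 - fy) +
        raster[cbind(i0 + 1, j0)] * (1 - fx) * fy +
        raster[cbind(i0 + 1, j0 + 1)] * fx * fy
    }
    v
  }

  means <- numeric(length(d_seq))
  short <- logical(length(d_seq))
  keep <- logical(length(d_seq))
  for (k in seq_along(d_seq)) {
    px <- ctr[1] + d_seq[k] * n_hat[1] + s_seq * t_hat[1]
    py <- ctr[2] + d_seq[k] * n_hat[2] + s_seq * t_hat[2]
    v <- bilinear(px, py)
    n_ok <- sum(!is.na(v))
    if (n_ok == 0) next
    keep[k] <- TRUE
    short[k] <- n_ok < length(v)
    means[k] <- mean(v, na.rm = TRUE)
  }
  if (!any(keep)) stop("no averaging line intersects the raster")
  d_kept <- d_seq[keep] - min(d_seq[keep])
  p <- luminance_profile(d_kept / px_per_um, means[keep])
  attr(p, "shortened") <- short[keep]
  p
}

#' Remove slow brightness trends, leaving band-scale residuals
#'
#' Image-to-image and across-image drifts in luminosity are removed by
#' subtracting a lowess smooth of brightness against distance; the
#' residual retains the band-scale oscillation. Two numerical choices keep
#' the trend estimate from eating the band signal: the default span covers
#' five nominal band widths, and the smoother sees a running mean of the
#' brightness over one nominal band width, which nulls most of the
#' (roughly zero-mean) band oscillation before the trend is fitted and
#' makes detrending nearly idempotent.
#'
#' @param p a [luminance_profile()] with at least 20 points.
#' @param span_fraction lowess span as a fraction of the profile; computed
#'   from `nominal_band_width_um` when `NULL`.
#' @param nominal_band_width_um sets the default span and the
#'   pre-averaging window.
#' @param pre_average_um band-suppression window for the trend fit, um
#'   (default one nominal band width; 0 disables).
#' @return The profile with a `residual` column added.
#' @export
detrend_profile <- function(p, span_fraction = NULL,
                            nominal_band_width_um = 34.7,
                            pre_average_um = nominal_band_width_um) {
  stopifnot(inherits(p, "luminance_profile"))
  if (nrow(p) < 20) stop("too few points to detrend (< 20)")
  extent <- diff(range(p$distance_um))
  if (is.null(span_fraction)) {
    span_fraction <- min(1, 5 * nominal_band_width_um / extent)
  }
  if (span_fraction * extent < 2 * nominal_band_width_um) {
    warning("lowess span below two band widths; residual may lose band signal")
  }
  y <- p$brightness
  if (pre_average_um > 0) {
    step <- stats::median(diff(p$distance_um))
    k <- max(1L, round(pre_average_um / step))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1L) y <- .runmean(y, k)
  }
  fit <- stats::lowess(p$distance_um, y, f = span_fraction)
  trend <- stats::approx(fit$x, fit$y, xout = p$distance_um, rule = 2)$y
  luminance_profile(p$distance_um, p$brightness,
                    residual = p$brightness - trend)
}

# centred running mean with shrinking symmetric windows at the edges
.runmean <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Prominence of local minima of `x` (equivalently peak prominence of -x).
# Returns a data.frame of index and prominence.
.minima_prominence <- function(x) {
  n <- length(x)
  y <- -x
  # local maxima of y, plateaus resolved to their leftmost point
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) idx <- c(idx, i)  # leftmost of plateau
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(idx)) {
    return(data.frame(index = integer(0), prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i0) {
    # walk left to the nearest strictly higher point (or the edge)
    l <- i0
    while (l > 1L && y[l - 1L] <= y[i0]) l <- l - 1L
    left_min <- min(y[max(1L, l - 1L):i0])
    r <- i0
    while (r < n && y[r + 1L] <= y[i0]) r <- r + 1L
    right_min <- min(y[i0:min(n, r + 1L)])
    y[i0] - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' A set of growth-band boundaries
#'
#' Ordered distances (micrometres, perpendicular to banding) delimiting
#' dark-light-dark fluorescence cycles, plus the inclination of banding to
#' the shell's exterior surface. Band widths outside the plausible 5-100
#' um range are flagged, not rejected.
#'
#' @param boundaries strictly increasing boundary positions, um.
#' @param angle_deg banding inclination to the exterior surface, degrees
#'   (default 11).
#' @return An object of class `band_set` with elements `boundaries`,
#'   `widths`, `angle_deg` and logical `implausible_width`.
#' @export
band_set <- function(boundaries, angle_deg = 11) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) >= 2 && any(diff(boundaries) <= 0)) {
    stop("band boundaries must be strictly increasing")
  }
  widths <- diff(boundaries)
  structure(
    list(boundaries = boundaries, widths = widths, angle_deg = angle_deg,
         implausible_width = widths < 5 | widths > 100),
    class = "band_set"
  )
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d bands over [%.1f, %.1f] um, angle %.1f deg\n",
              length(x$widths),
              if (length(x$boundaries)) min(x$boundaries) else NA,
              if (length(x$boundaries)) max(x$boundaries) else NA,
              x$angle_deg))
  invisible(x)
}

#' @rdname band_set
#' @param x an object.
#' @export
n_bands <- function(x) {
  stopifnot(inherits(x, "band_set"))
  length(x$widths)
}

#' Segment growth bands from a detrended luminance profile
#'
#' A band is one low-high-low fluorescence cycle, so boundaries are placed
#' at residual minima (the dark loci). Minima qualify when their
#' prominence reaches the threshold; ties and plateaus resolve to the
#' leftmost (youngest) position. Consecutive qualifying minima then
#' delimit one band each.
#'
#' @param p a detrended [luminance_profile()].
#' @param prominence minimum prominence in grayscale units; default half
#'   the robust (MAD-based) standard deviation of the residual.
#' @param smooth_um half-band-scale running-mean window applied to the
#'   residual before minima detection, um; suppresses point noise while
#'   leaving band-scale minima in place (0 disables).
#' @param angle_deg banding inclination passed through to [band_set()].
#' @return A [band_set()]; empty when fewer than two qualifying minima.
#' @export
segment_bands <- function(p, prominence = NULL, smooth_um = 5,
                          angle_deg = 11) {
  stopifnot(inherits(p, "luminance_profile"))
  if (is.null(p$residual)) stop("detrend the profile first (no residual)")
  r <- p$residual
  if (smooth_um > 0) {
    step <- stats::median(diff(p$distance_um))
    k <- max(1L, round(smooth_um / step))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1L) r <- .runmean(r, k)
  }
  if (is.null(prominence)) {
    prominence <- 0.5 * stats::mad(r)
  }
  mins <- .minima_prominence(r)
  mins <- mins[mins$prominence >= prominence & mins$prominence > 0, ,
               drop = FALSE]
  if (nrow(mins) < 2) {
    return(band_set(numeric(0), angle_deg = angle_deg))
  }
  band_set(p$distance_um[mins$index], angle_deg = angle_deg)
}

#' Descriptive statistics of band widths
#'
#' @param b a [band_set()] with at least one band.
#' @return A one-row data.frame: n, mean, sd, min, max (widths in um,
#'   measured normal to banding).
#' @export
band_width_stats <- function(b) {
  stopifnot(inherits(b, "band_set"))
  w <- b$widths
  if (!length(w)) stop("empty band set")
  data.frame(n = length(w), mean = mean(w),
             sd = if (length(w) > 1) stats::sd(w) else 0,
             min = min(w), max = max(w))
}

#' Apertural growth per band from band width and inclination
#'
#' Band widths are measured normal to banding, but growth rates in the
#' literature are apertural (along the exterior surface). With banding
#' inclined at `angle_deg` to the surface, one band of width `w` normal to
#' banding corresponds to `w / sin(angle)` of apertural extension.
#'
#' @param width_um band width(s) normal to banding, um.
#' @param angle_deg inclination in (0, 90].
#' @return Apertural growth, um per band.
#' @examples
#' apertural_growth(34.7, 11)  # ~182
#' @export
apertural_growth <- function(width_um, angle_deg = 11) {
  if (any(angle_deg <= 0) || any(angle_deg > 90)) {
    stop("angle must lie in (0, 90] degrees")
  }
  width_um / sin(angle_deg * pi / 180)
}

#' Build a 24-hour-per-band chronology from segmented bands
#'
#' Treats each dark-light-dark cycle as one day: time is piecewise linear
#' in distance, accruing 24 h per band, uniform within a band, zero at the
#' youngest boundary and increasing toward older shell.
#'
#' @param b a [band_set()] with at least one band.
#' @param hours_per_band hours per cycle (24 for daily banding).
#' @return An object of class `chronology` with `boundaries`,
#'   `band_edges_hours` and `hours_per_band`.
#' @export
build_chronology <- function(b, hours_per_band = 24) {
  stopifnot(inherits(b, "band_set"))
  if (!length(b$widths)) stop("cannot build a chronology from 0 bands")
  structure(
    list(boundaries = b$boundaries,
         band_edges_hours = hours_per_band * (seq_along(b$boundaries) - 1),
         hours_per_band = hours_per_band),
    class = "chronology"
  )
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %d bands, %.0f h/band, span %.0f h\n",
              length(x$boundaries) - 1, x$hours_per_band,
              max(x$band_edges_hours)))
  invisible(x)
}

#' Map shell distance to hours of growth (and back)
#'
#' Linear interpolation within bands of the chronology built by
#' [build_chronology()]. Distances outside the banded interval are
#' extrapolated at the nearest band's rate and flagged in the
#' `extrapolated` attribute.
#'
#' @param chron a `chronology`.
#' @param distance_um distances perpendicular to banding, um.
#' @param hours hours of growth (for the inverse).
#' @return Hours (or distances), with logical attribute `extrapolated`.
#' @export
hours_at_distance <- function(chron, distance_um) {
  stopifnot(inherits(chron, "chronology"))
  b <- chron$boundaries
  h <- chron$band_edges_hours
  out <- stats::approx(b, h, xout = distance_um, rule = 2)$y
  extra <- distance_um < min(b) | distance_um > max(b)
  if (any(extra)) {
    # extend at the first/last band's rate
    r_lo <- chron$hours_per_band / (b[2] - b[1])
    nb <- length(b)
    r_hi <- chron$hours_per_band / (b[nb] - b[nb - 1])
    lo <- extra & distance_um < min(b)
    hi <- extra & distance_um > max(b)
    out[lo] <- h[1] - (min(b) - distance_um[lo]) * r_lo
    out[hi] <- h[nb] + (distance_um[hi] - max(b)) * r_hi
  }
  attr(out, "extrapolated") <- extra
  out
}

#' @rdname hours_at_distance
#' @export
distance_at_hours <- function(chron, hours) {
  stopifnot(inherits(chron, "chronology"))
  b <- chron$boundaries
  h <- chron$band_edges_hours
  out <- stats::approx(h, b, xout = hours, rule = 2)$y
  extra <- hours < min(h) | hours > max(h)
  if (any(extra)) {
    r_lo <- (b[2] - b[1]) / chron$hours_per_band
    nb <- length(b)
    r_hi <- (b[nb] - b[nb - 1]) / chron$hours_per_band
    lo <- extra & hours < min(h)
    hi <- extra & hours > max(h)
    out[lo] <- b[1] - (min(h) - hours[lo]) * r_lo
    out[hi] <- b[nb] + (hours[hi] - max(h)) * r_hi
  }
  attr(out, "extrapolated") <- extra
  out
}

#' Time span integrated by one analysis spot
#'
#' A spot of finite diameter integrates shell precipitated over
#' `24 h * spot_diameter / band_width` for daily bands: the fundamental
#' temporal resolution of in-situ sampling.
#'
#' @param spot_diameter_um analysis spot diameter, um.
#' @param band_width_um daily band width normal to banding, um.
#' @return Hours of growth represented by one spot.
#' @examples
#' pit_time_resolution(10, 34.7)  # ~7 h
#' @export
pit_time_resolution <- function(spot_diameter_um, band_width_um) {
  if (any(spot_diameter_um <= 0) || any(band_width_um <= 0)) {
    stop("spot diameter and band width must be positive")
  }
  24 * spot_diameter_um / band_width_um
}
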