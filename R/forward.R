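#' A depth trajectory
#'
#' Time series of habitat depth, e.g. from acoustic telemetry or a
#' simulated migration pattern.
#'
#' @param time_h strictly increasing times, hours.
#' @param depth_m non-negative depths, metres.
#' @return A data.frame classed `depth_trajectory`.
#' @export
depth_trajectory <- function(time_h, depth_m) {
  stopifnot(length(time_h) == length(depth_m))
  if (any(diff(time_h) <= 0)) stop("time grid must be strictly increasing")
  if (any(depth_m < 0)) stop("depths must be non-negative")
  df <- data.frame(time_h = as.numeric(time_h),
                   depth_m = as.numeric(depth_m))
  class(df) <- c("depth_trajectory", "data.frame")
  df
}

#' Equilibrium delta-18O series along a depth trajectory
#'
#' Maps each depth to its temperature through the column's linear profile
#' and then to the delta-18O of aragonite precipitating in equilibrium at
#' that temperature (deeper = colder = isotopically heavier). Depths below
#' the column floor are clipped and flagged.
#'
#' @param traj a [depth_trajectory()].
#' @param column a [water_column()].
#' @param constants constant set from [iso_constants()].
#' @return A data.frame (`predicted_series`) with `time_h`, `depth_m`,
#'   `temp_c` and `true_delta` (per mil VPDB); attribute `clipped` marks
#'   clipped depths.
#' @export
delta_series <- function(traj, column, constants = iso_constants()) {
  stopifnot(inherits(traj, "depth_trajectory"),
            inherits(column, "water_column"))
  clipped <- traj$depth_m > column$max_depth
  if (any(clipped)) {
    warning(sum(clipped), " depth value(s) clipped to the column floor")
  }
  z <- pmin(traj$depth_m, column$max_depth)
  temp <- temperature_at_depth(z, column)
  d_arg <- equilibrium_delta_arg(temp, column$delta_sw, constants)
  out <- data.frame(time_h = traj$time_h, depth_m = z, temp_c = temp,
                    true_delta = as.numeric(vsmow_to_vpdb(d_arg, constants)))
  class(out) <- c("predicted_series", "data.frame")
  attr(out, "clipped") <- clipped
  out
}

#' Spot time-averaging of a delta-18O series
#'
#' An analysis spot integrates all shell grown while the spot's footprint
#' was being precipitated, smearing fast excursions: the smeared value at
#' time `t` is the average of the true series over `[t - tau/2, t + tau/2]`.
#' Uniform (boxcar) weighting treats growth as constant across the spot;
#' `"chord"` weights by the chord length of a circular spot. Windows
#' truncated at the series ends are renormalised and flagged.
#'
#' @param series a data.frame with `time_h` and `true_delta` (e.g. from
#'   [delta_series()]).
#' @param window_h averaging window tau, hours (see [window_from_spot()]).
#' @param weighting `"boxcar"` (default) or `"chord"`.
#' @return The series with a `smeared_delta` column and a `window_h`
#'   attribute; logical attribute `truncated` marks edge windows.
#' @export
spot_average <- function(series, window_h, weighting = c("boxcar", "chord")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(series),
            all(c("time_h", "true_delta") %in% names(series)))
  if (window_h <= 0) stop("window must be positive")
  t <- series$time_h
  v <- series$true_delta
  step <- stats::median(diff(t))
  if (window_h < 2 * step) {
    warning("window shorter than two grid steps; returning the series unsmoothed")
    series$smeared_delta <- v
    attr(series, "window_h") <- window_h
    attr(series, "truncated") <- rep(FALSE, length(t))
    return(series)
  }
  half <- window_h / 2
  n <- length(t)
  smeared <- numeric(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    sel <- which(t >= t[i] - half & t <= t[i] + half)
    truncated[i] <- (t[i] - half < t[1]) || (t[i] + half > t[n])
    if (weighting == "boxcar") {
      smeared[i] <- mean(v[sel])
    } else {
      s <- (t[sel] - t[i]) / half
      w <- sqrt(pmax(0, 1 - s^2))
      smeared[i] <- sum(w * v[sel]) / sum(w)
    }
  }
  series$smeared_delta <- smeared
  attr(series, "window_h") <- window_h
  attr(series, "truncated") <- truncated
  series
}

#' Averaging window implied by a spot diameter and growth rate
#'
#' `tau = 24 h * spot_diameter / growth_rate`: the time it takes the shell
#' to grow one spot diameter.
#'
#' @param spot_diameter_um spot diameter, um.
#' @param growth_rate_um_per_day band-normal growth rate, um/day.
#' @return Window length tau, hours.
#' @examples
#' window_from_spot(10, 35)  # 6.86 h
#' @export
window_from_spot <- function(spot_diameter_um, growth_rate_um_per_day) {
  if (any(spot_diameter_um <= 0) || any(growth_rate_um_per_day <= 0)) {
    stop("spot diameter and growth rate must be positive")
  }
  24 * spot_diameter_um / growth_rate_um_per_day
}

#' Sample a smeared series as discrete synthetic pits
#'
#' Bridges the forward model to the inference machinery: reads the smeared
#' series at the requested pit times and adds Gaussian analytical noise
#' with the stated 2SD. Times outside the series support are dropped with
#' a flag.
#'
#' @param series output of [spot_average()].
#' @param pit_times times of synthetic analyses, hours.
#' @param noise_2sd analytical precision, per mil (2 standard deviations).
#' @param seed optional integer for reproducibility.
#' @return A pit table with `analysis`, `time_h`, `d18O_vpdb` and
#'   `true_smeared` columns; attribute `dropped` lists out-of-support
#'   times.
#' @export
sample_as_pits <- function(series, pit_times, noise_2sd = 0.3, seed = NULL) {
  stopifnot("smeared_delta" %in% names(series))
  if (!is.null(seed)) set.seed(seed)
  inside <- pit_times >= min(series$time_h) & pit_times <= max(series$time_h)
  dropped <- pit_times[!inside]
  if (length(dropped)) {
    warning(length(dropped), " pit time(s) outside the series support dropped")
  }
  pt <- pit_times[inside]
  sm <- stats::approx(series$time_h, series$smeared_delta, xout = pt)$y
  out <- data.frame(
    analysis = sprintf("sim-%d", seq_along(pt)),
    time_h = pt,
    true_smeared = sm,
    d18O_vpdb = sm + stats::rnorm(length(pt), 0, noise_2sd / 2),
    stringsAsFactors = FALSE
  )
  out <- as_pit_table(out)
  attr(out, "dropped") <- dropped
  out
}
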