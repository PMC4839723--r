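#' Equilibrium aragonite-water fractionation, 1000 ln(alpha)
#'
#' The temperature dependence of the aragonite-water oxygen isotope
#' fractionation factor, as the linear calibration
#' \deqn{1000\,\ln\alpha = a\,(10^3/T) - b}
#' with `T` in kelvin. Strictly decreasing in temperature.
#'
#' @param temp_k temperature in kelvin; must lie in (250, 350).
#' @param constants constant set from [iso_constants()].
#' @return 1000 ln(alpha), per mil equivalent.
#' @examples
#' thousand_ln_alpha(298.15)
#' @export
thousand_ln_alpha <- function(temp_k, constants = iso_constants()) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 250) || any(temp_k >= 350)) {
    stop("temperature outside the physical range (250, 350) K")
  }
  constants$kim_a * (1000 / temp_k) - constants$kim_b
}

#' Equilibrium aragonite delta-18O at a given temperature
#'
#' Predicts the delta-18O of aragonite precipitated in oxygen isotope
#' equilibrium with water of composition `delta_sw` at temperature
#' `temp_c`, using the fractionation calibration and the definition
#' \eqn{\alpha = (1000 + \delta_{arg}) / (1000 + \delta_w)} with both
#' deltas on the VSMOW scale.
#'
#' @param temp_c water temperature in degrees Celsius, in (-2, 40).
#' @param delta_sw seawater delta-18O; a [delta18O()] VSMOW water value, or
#'   a bare numeric interpreted as per mil VSMOW (water).
#' @param constants constant set from [iso_constants()].
#' @return A [delta18O()] aragonite value on the VSMOW scale. Convert with
#'   [vsmow_to_vpdb()] for the customary carbonate scale.
#' @examples
#' d <- equilibrium_delta_arg(22, -0.2)
#' vsmow_to_vpdb(d)   # about -1.2 per mil VPDB
#' @export
equilibrium_delta_arg <- function(temp_c, delta_sw,
                                  constants = iso_constants()) {
  if (any(temp_c <= -2) || any(temp_c >= 40)) {
    stop("temperature outside the calibration range (-2, 40) degC")
  }
  delta_sw <- .as_delta(delta_sw, "VSMOW", "water")
  .assert_scale(delta_sw, "VSMOW")
  if (delta_phase(delta_sw) != "water") {
    stop("delta_sw must be a water value")
  }
  lna <- thousand_ln_alpha(temp_c + 273.15, constants) / 1000
  delta18O((1000 + as.numeric(delta_sw)) * exp(lna) - 1000,
           "VSMOW", "aragonite")
}

#' Temperature of equilibrium precipitation from aragonite and water deltas
#'
#' Inverts the fractionation calibration: given the measured aragonite
#' delta-18O and the ambient water delta-18O, returns the temperature at
#' which equilibrium precipitation would produce that pair. This is the
#' workhorse of depth inference: colder (deeper) water gives higher
#' aragonite delta-18O.
#'
#' @param d_arg aragonite [delta18O()] on either scale (VPDB values are
#'   converted internally).
#' @param delta_sw seawater delta-18O as in [equilibrium_delta_arg()].
#' @param constants constant set from [iso_constants()].
#' @return Temperature in degrees Celsius.
#' @examples
#' temperature_from_delta(delta18O(0.9, "VPDB"), 0.5)   # ~15.3 degC
#' temperature_from_delta(delta18O(-1.6, "VPDB"), 0.5)  # ~27.5 degC
#' @export
temperature_from_delta <- function(d_arg, delta_sw,
                                   constants = iso_constants()) {
  if (!is_delta18O(d_arg)) stop("d_arg must be a delta18O object")
  if (delta_phase(d_arg) != "aragonite") {
    stop("d_arg must be an aragonite value")
  }
  delta_sw <- .as_delta(delta_sw, "VSMOW", "water")
  d_arg_smow <- .to_vsmow(d_arg, constants)
  alpha <- (1000 + as.numeric(d_arg_smow)) / (1000 + as.numeric(delta_sw))
  denom <- 1000 * log(alpha) + constants$kim_b
  if (any(denom <= 0)) {
    stop("fractionation outside the invertible range of the calibration")
  }
  constants$kim_a * 1000 / denom - 273.15
}

#' A linear water-column model
#'
#' Describes the water column as a surface temperature, a constant thermal
#' gradient (temperature decreasing with depth), a constant seawater
#' delta-18O and a maximum habitable depth.
#'
#' The default gradient of 0.03 degC/m reproduces the canonical arithmetic
#' that a ~12 degC temperature span corresponds to ~400 m of depth change;
#' observed mean profiles near New Caledonia (17.5 degC over 800 m) imply
#' ~0.022 degC/m, so site-specific gradients should be supplied where known.
#'
#' @param surface_temp sea-surface temperature, degC.
#' @param gradient cooling rate with depth, degC per metre; must be > 0.
#' @param delta_sw seawater delta-18O (per mil VSMOW, water), constant with
#'   depth.
#' @param max_depth habitat floor in metres, in (0, 1000]. The 750 m
#'   default approximates the implosion-depth limit of nautilid habitat.
#' @return An object of class `water_column`.
#' @examples
#' water_column(27.6)
#' @export
water_column <- function(surface_temp, gradient = 0.03, delta_sw = 0.5,
                         max_depth = 750) {
  stopifnot(is.numeric(surface_temp), length(surface_temp) == 1L)
  if (gradient <= 0) stop("thermal gradient must be positive")
  if (max_depth <= 0 || max_depth > 1000) {
    stop("max_depth must lie in (0, 1000] m")
  }
  structure(
    list(surface_temp = surface_temp, gradient = gradient,
         delta_sw = .as_delta(delta_sw, "VSMOW", "water"),
         max_depth = max_depth),
    class = "water_column"
  )
}

#' @export
print.water_column <- function(x, ...) {
  cat(sprintf(
    "<water_column> surface %.1f degC, gradient %.3f degC/m, d18Osw %.2f permil VSMOW, floor %.0f m\n",
    x$surface_temp, x$gradient, as.numeric(x$delta_sw), x$max_depth))
  invisible(x)
}

#' Depth implied by a temperature in a linear water column
#'
#' Inverts the column's linear temperature profile,
#' `z = (surface_temp - T) / gradient`, clipping to `[0, max_depth]`. The
#' returned vector carries a logical `clipped` attribute marking values
#' that hit either bound.
#'
#' @param temp_c temperature(s) in degC; must not exceed the surface
#'   temperature.
#' @param column a [water_column()].
#' @return Depth in metres, with attribute `clipped`.
#' @examples
#' col <- water_column(27.6, gradient = 0.03)
#' depth_from_temperature(15.6, col)  # 400 m
#' @export
depth_from_temperature <- function(temp_c, column) {
  stopifnot(inherits(column, "water_column"))
  if (any(temp_c > column$surface_temp)) {
    stop("temperature exceeds the surface temperature of the column")
  }
  z <- (column$surface_temp - temp_c) / column$gradient
  clipped <- z < 0 | z > column$max_depth
  z <- pmin(pmax(z, 0), column$max_depth)
  attr(z, "clipped") <- clipped
  z
}

#' @rdname depth_from_temperature
#' @param depth_m depth(s) in metres within `[0, max_depth]`.
#' @export
temperature_at_depth <- function(depth_m, column) {
  stopifnot(inherits(column, "water_column"))
  if (any(depth_m < 0)) stop("depth must be non-negative")
  column$surface_temp - column$gradient * pmin(depth_m, column$max_depth)
}

#' Recalibrate a standard value between acid fractionation factors
#'
#' Working-standard delta-18O values assigned through phosphoric acid
#' digestion depend on the acid-CO2/carbonate fractionation factor used.
#' Moving a standard value from an older factor to a revised one multiplies
#' the absolute ratio by their quotient:
#' `delta_new = (1000 + delta_old) * alpha_old / alpha_new - 1000`.
#'
#' @param delta_old assigned value under `alpha_old`, per mil VSMOW.
#' @param alpha_old,alpha_new acid fractionation factors (near 1.01).
#' @return Recalibrated value, per mil VSMOW.
#' @examples
#' recalibrate_standard(20.03, 1.01034, 1.01063)  # 19.74
#' @export
recalibrate_standard <- function(delta_old, alpha_old, alpha_new) {
  if (alpha_old <= 0 || alpha_new <= 0) {
    stop("fractionation factors must be positive")
  }
  (1000 + delta_old) * (alpha_old / alpha_new) - 1000
}
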