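#' Calibration constants for oxygen isotope thermometry
#'
#' Returns the constant set used throughout the package: the aragonite-water
#' equilibrium fractionation calibration (Kim et al. aragonite calibration,
#' valid 0-40 degC), the VPDB to VSMOW scale conversion after Coplen, the
#' absolute 18O/16O ratio of VSMOW used to define raw SIMS delta values, and
#' the phosphoric acid fractionation factors used to (re)assign aragonite
#' working-standard values.
#'
#' Any element can be overridden, e.g. to swap in an alternative carbonate
#' calibration, either via `...` or by passing a `calibration:` block parsed
#' from a YAML config (see [read_pipeline_config()]).
#'
#' @param ... named overrides for individual constants.
#' @return A list with elements `kim_a` (10^3 K), `kim_b` (per mil
#'   equivalent), `vpdb_slope`, `vpdb_offset` (per mil), `ref_ratio`
#'   (18O/16O of VSMOW), `acid_alpha_old`, `acid_alpha_new`.
#' @examples
#' iso_constants()$vpdb_offset  # 30.91
#' iso_constants(kim_a = 17.9)$kim_a
#' @export
iso_constants <- function(...) {
  const <- list(
    kim_a = 17.88,            # slope of 1000 ln(alpha) vs 1000/T
    kim_b = 31.14,            # intercept of 1000 ln(alpha)
    vpdb_slope = 1.03091,     # VSMOW = slope * VPDB + offset
    vpdb_offset = 30.91,
    ref_ratio = 0.00200520,   # 18O/16O of VSMOW
    acid_alpha_old = 1.01034, # acid-CO2/aragonite at 25 degC, older value
    acid_alpha_new = 1.01063  # acid-CO2/aragonite at 25 degC, revised value
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  if (length(over)) {
    bad <- setdiff(names(over), names(const))
    if (length(bad)) {
      stop("unknown calibration constant(s): ", paste(bad, collapse = ", "))
    }
    const[names(over)] <- over
  }
  stopifnot(all(vapply(const, function(x) is.numeric(x) && x > 0, logical(1))))
  const
}

#' A delta-18O value bound to its reference scale and phase
#'
#' Oxygen isotope ratios are meaningless without their reference scale
#' (carbonates are customarily reported against VPDB, waters against VSMOW)
#' and the phase they describe. `delta18O` wraps a numeric vector with both
#' tags so that scale arithmetic is explicit: conversion functions refuse
#' inputs on the wrong scale instead of silently mixing scales, and
#' conversions never change the phase.
#'
#' @param value numeric vector of delta values in per mil. Must exceed
#'   -1000 (the physical lower bound of the delta notation).
#' @param scale `"VPDB"` or `"VSMOW"`.
#' @param phase `"aragonite"`, `"water"` or `"co2"`.
#' @return An object of class `delta18O`.
#' @examples
#' d <- delta18O(-0.7, "VPDB", "aragonite")
#' vpdb_to_vsmow(d)
#' @export
delta18O <- function(value, scale = c("VPDB", "VSMOW"),
                     phase = c("aragonite", "water", "co2")) {
  scale <- match.arg(toupper(scale[1]), c("VPDB", "VSMOW"))
  phase <- match.arg(phase)
  if (!is.numeric(value)) stop("delta value must be numeric")
  if (any(value <= -1000, na.rm = TRUE)) {
    stop("delta values must be > -1000 per mil")
  }
  structure(as.numeric(value), scale = scale, phase = phase,
            class = "delta18O")
}

#' @export
print.delta18O <- function(x, ...) {
  cat(sprintf("<delta18O %s, %s>\n", attr(x, "scale"), attr(x, "phase")))
  print(as.numeric(x), ...)
  invisible(x)
}

#' @rdname delta18O
#' @param x object to test or extract from.
#' @export
is_delta18O <- function(x) inherits(x, "delta18O")

#' @rdname delta18O
#' @export
delta_scale <- function(x) {
  stopifnot(is_delta18O(x))
  attr(x, "scale")
}

#' @rdname delta18O
#' @export
delta_phase <- function(x) {
  stopifnot(is_delta18O(x))
  attr(x, "phase")
}

.assert_scale <- function(d, scale) {
  if (!is_delta18O(d)) stop("expected a delta18O object; got ", class(d)[1])
  if (delta_scale(d) != scale) {
    stop("scale error: expected a ", scale, " value, got ", delta_scale(d))
  }
  invisible(d)
}

# Coerce a bare numeric into a tagged delta, used where an interface
# documents the scale/phase it assumes (e.g. seawater delta as VSMOW water).
.as_delta <- function(x, scale, phase) {
  if (is_delta18O(x)) return(x)
  delta18O(x, scale, phase)
}

#' Convert delta-18O between the VPDB and VSMOW scales
#'
#' Applies the linear scale conversion
#' \deqn{\delta^{18}O_{VSMOW} = 1.03091\,\delta^{18}O_{VPDB} + 30.91}
#' (or its exact inverse). The phase tag is preserved; the scale tag is
#' updated. Passing a value already on the target scale returns it
#' unchanged; passing a value on the wrong source scale is an error.
#'
#' @param d a [delta18O()] value on the source scale.
#' @param constants constant set from [iso_constants()].
#' @return A [delta18O()] value on the target scale, same phase.
#' @examples
#' vpdb_to_vsmow(delta18O(0, "VPDB"))    # 30.91
#' vsmow_to_vpdb(delta18O(30.91, "VSMOW"))
#' @export
vpdb_to_vsmow <- function(d, constants = iso_constants()) {
  .assert_scale(d, "VPDB")
  delta18O(constants$vpdb_slope * as.numeric(d) + constants$vpdb_offset,
           "VSMOW", delta_phase(d))
}

#' @rdname vpdb_to_vsmow
#' @export
vsmow_to_vpdb <- function(d, constants = iso_constants()) {
  .assert_scale(d, "VSMOW")
  delta18O((as.numeric(d) - constants$vpdb_offset) / constants$vpdb_slope,
           "VPDB", delta_phase(d))
}

# Return the value on the VSMOW scale whatever the input scale.
.to_vsmow <- function(d, constants = iso_constants()) {
  if (delta_scale(d) == "VSMOW") d else vpdb_to_vsmow(d, constants)
}
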