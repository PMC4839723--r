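#' Assign analysis pits to growth bands
#'
#' Each pit is matched to the band whose half-open interval
#' `[boundary_k, boundary_k+1)` contains its centre distance; a pit
#' exactly on a boundary therefore belongs to the older band (distance
#' increases toward older shell). Pits outside the banded interval are
#' returned unassigned.
#'
#' @param pits a pit table with a `dist_um` column.
#' @param bands a [band_set()].
#' @return A list with `assigned` (the pit table plus a `band_index`
#'   column, 1 = youngest band) and `unassigned`.
#' @export
assign_pits_to_bands <- function(pits, bands) {
  pits <- as_pit_table(as.data.frame(pits))
  stopifnot(inherits(bands, "band_set"))
  if (!"dist_um" %in% names(pits)) stop("no dist_um column")
  b <- bands$boundaries
  if (length(b) < 2) stop("band set has no bands")
  idx <- findInterval(pits$dist_um, b, left.open = FALSE)
  inside <- pits$dist_um >= b[1] & pits$dist_um < b[length(b)]
  out <- pits
  out$band_index <- ifelse(inside, idx, NA_integer_)
  list(assigned = out[inside, , drop = FALSE],
       unassigned = out[!inside, , drop = FALSE])
}

#' Within-band delta-18O ranges and precision exceedance
#'
#' For every band holding at least `min_pits` analyses, computes the
#' max-minus-min spread of corrected delta-18O and whether it exceeds the
#' instrumental precision threshold. Aggregates report how many bands show
#' variation beyond precision - the signature of sub-daily environmental
#' change - together with the mean and maximum within-band range.
#'
#' @param assigned a pit table with `band_index` (from
#'   [assign_pits_to_bands()]) and a delta column.
#' @param precision_threshold per mil; a band "exceeds precision" when its
#'   range is strictly larger. The default 0.6 is the 2SD spot-to-spot
#'   precision of the reference dataset's headline count; per-spot 2SD
#'   values near 0.3 are typical, so the threshold is deliberately
#'   explicit.
#' @param min_pits minimum analyses for a band to qualify (2; use 3 for
#'   the stricter within-band comparison).
#' @param value delta column name.
#' @return A list with `per_band` (band_index, n_pits, delta_range,
#'   exceeds_precision) and `aggregate` (n_bands, n_exceeding, mean_range,
#'   max_range, threshold).
#' @export
within_band_ranges <- function(assigned, precision_threshold = 0.6,
                               min_pits = 2, value = "d18O_vpdb") {
  assigned <- as.data.frame(assigned)
  if (!"band_index" %in% names(assigned)) stop("no band_index column")
  if (!value %in% names(assigned)) stop("no column ", value)
  sp <- split(assigned[[value]], assigned$band_index)
  sp <- sp[vapply(sp, length, integer(1)) >= min_pits]
  if (!length(sp)) {
    per_band <- data.frame(band_index = integer(0), n_pits = integer(0),
                           delta_range = numeric(0),
                           exceeds_precision = logical(0))
  } else {
    per_band <- data.frame(
      band_index = as.integer(names(sp)),
      n_pits = vapply(sp, length, integer(1)),
      delta_range = vapply(sp, function(v) diff(range(v)), numeric(1)),
      row.names = NULL
    )
    per_band$exceeds_precision <- per_band$delta_range > precision_threshold
  }
  list(
    per_band = per_band,
    aggregate = data.frame(
      n_bands = nrow(per_band),
      n_exceeding = sum(per_band$exceeds_precision),
      mean_range = if (nrow(per_band)) mean(per_band$delta_range) else NA_real_,
      max_range = if (nrow(per_band)) max(per_band$delta_range) else NA_real_,
      threshold = precision_threshold
    )
  )
}

#' Transect-wide delta-18O extremes
#'
#' @param pits a pit table (QC-passing analyses).
#' @param value delta column name.
#' @return A one-row data.frame: min, max, range (per mil).
#' @export
transect_range <- function(pits, value = "d18O_vpdb") {
  pits <- as.data.frame(pits)
  if (!nrow(pits)) stop("empty pit table")
  if (!value %in% names(pits)) stop("no column ", value)
  v <- pits[[value]]
  data.frame(min = min(v), max = max(v), range = diff(range(v)))
}

#' Temperature and depth envelope of a transect
#'
#' Converts the transect's delta-18O extremes to equilibrium temperatures
#' (high delta = cold = deep; low delta = warm = shallow) and the implied
#' temperature span to a minimum depth extent through the column's thermal
#' gradient. Because spot analyses time-average and sampling is discrete,
#' both spans are lower bounds on the water-column excursion actually
#' traversed.
#'
#' @param pits a QC-passed pit table with VPDB deltas.
#' @param delta_sw seawater delta-18O (per mil VSMOW water or
#'   [delta18O()]); defaults to the column's value.
#' @param column a [water_column()].
#' @param value delta column name.
#' @param constants constant set from [iso_constants()].
#' @return A one-row data.frame: delta_min, delta_max, temp_warm,
#'   temp_cold, temp_span, depth_extent_m.
#' @export
envelope <- function(pits, column, delta_sw = NULL, value = "d18O_vpdb",
                     constants = iso_constants()) {
  stopifnot(inherits(column, "water_column"))
  if (is.null(delta_sw)) delta_sw <- column$delta_sw
  tr <- transect_range(pits, value = value)
  t_warm <- temperature_from_delta(delta18O(tr$min, "VPDB", "aragonite"),
                                   delta_sw, constants)
  t_cold <- temperature_from_delta(delta18O(tr$max, "VPDB", "aragonite"),
                                   delta_sw, constants)
  span <- t_warm - t_cold
  data.frame(delta_min = tr$min, delta_max = tr$max,
             temp_warm = t_warm, temp_cold = t_cold, temp_span = span,
             depth_extent_m = span / column$gradient)
}

#' Correlation between delta-18O and band fluorescence
#'
#' If delta-18O variation were physiological (tied to the organic-matter
#' rhythm that produces banding) it should track CLFM brightness; depth
#' migration predicts no such coupling. Reports Pearson and Spearman
#' statistics as diagnostics.
#'
#' @param pits a pit table with `clfm_greyscale` and a delta column.
#' @param value delta column name.
#' @return A data.frame with one row per test: method, estimate, p_value,
#'   n. Both estimates are `NA` (flagged via a warning) when either
#'   column is constant.
#' @export
fluorescence_correlation <- function(pits, value = "d18O_vpdb") {
  pits <- as.data.frame(pits)
  if (!"clfm_greyscale" %in% names(pits)) stop("no clfm_greyscale column")
  if (!value %in% names(pits)) stop("no column ", value)
  ok <- stats::complete.cases(pits[[value]], pits$clfm_greyscale)
  x <- pits[[value]][ok]; y <- pits$clfm_greyscale[ok]
  if (length(x) < 3) stop("need at least 3 pits with fluorescence values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant column: correlation undefined")
    return(data.frame(method = c("pearson", "spearman"),
                      estimate = NA_real_, p_value = NA_real_,
                      n = length(x)))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p_value = c(pe$p.value, sp$p.value),
             n = length(x))
}
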