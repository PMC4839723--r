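#' Verify the raw-to-VSMOW-to-VPDB reduction chain of a printed pit table
#'
#' Published SIMS tables print the raw delta, the bracket-and-bias
#' corrected VSMOW delta and the VPDB delta of each analysis, all rounded
#' to 0.1 per mil. This check confirms that the printed columns are
#' mutually consistent with the package's reduction chain:
#'
#' * VPDB leg: converting the printed VSMOW value through the exact scale
#'   conversion must agree with the printed VPDB value to printed
#'   rounding. Because both columns are rounded to 0.1 per mil, the
#'   attainable bound is half an ulp on the output plus the propagated
#'   half-ulp of the input, `0.05 + 0.05/1.03091` (about 0.098 per mil);
#'   this is the default tolerance.
#' * Bracket leg: the per-row correction `VSMOW - raw` must be coherent
#'   with bracket structure, i.e. within any one session/transect group
#'   it may take only a few distinct values (one per bracket, rounded).
#'
#' @param pits a pit table with `d18O_raw`, `d18O_vsmow`, `d18O_vpdb` and
#'   (optionally) `date` columns.
#' @param tol_vpdb tolerance for the VPDB leg, per mil.
#' @param max_brackets_per_group maximum distinct (0.1-rounded) bracket
#'   corrections tolerated within one session/transect group.
#' @param constants constant set from [iso_constants()].
#' @return A list: `rows` (per-row deviations), `groups` (per-group
#'   bracket-correction counts), and logical `ok`.
#' @export
verify_table_chain <- function(pits,
                               tol_vpdb = 0.05 + 0.05 / 1.03091,
                               max_brackets_per_group = 4,
                               constants = iso_constants()) {
  pits <- as.data.frame(pits)
  need <- c("d18O_raw", "d18O_vsmow", "d18O_vpdb")
  if (!all(need %in% names(pits))) {
    stop("chain check needs columns: ", paste(need, collapse = ", "))
  }
  vpdb_hat <- (pits$d18O_vsmow - constants$vpdb_offset) / constants$vpdb_slope
  rows <- data.frame(
    analysis = pits$analysis,
    dev_vpdb = vpdb_hat - pits$d18O_vpdb,
    correction = pits$d18O_vsmow - pits$d18O_raw
  )
  rows$ok_vpdb <- abs(rows$dev_vpdb) <= tol_vpdb

  transect <- sub("-.*$", "", pits$analysis)
  session <- if ("date" %in% names(pits)) as.character(pits$date) else ""
  key <- paste(session, transect, sep = "|")
  groups <- do.call(rbind, lapply(split(rows$correction, key), function(v) {
    data.frame(n = length(v),
               n_corrections = length(unique(round(v, 1))),
               spread = diff(range(v)))
  }))
  groups$group <- rownames(groups)
  rownames(groups) <- NULL
  groups$ok <- groups$n_corrections <= max_brackets_per_group
  list(rows = rows, groups = groups,
       ok = all(rows$ok_vpdb) && all(groups$ok))
}
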