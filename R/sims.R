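#' Raw SIMS delta-18O from a measured isotope ratio
#'
#' Raw SIMS deltas are defined against the absolute 18O/16O ratio of VSMOW:
#' `delta_raw = (ratio / ref_ratio - 1) * 1000`. [ratio_from_raw_delta()]
#' is the exact inverse.
#'
#' @param ratio measured 18O/16O ratio(s); must be positive.
#' @param delta_raw raw delta value(s), per mil.
#' @param constants constant set from [iso_constants()].
#' @return Per mil raw delta (or the ratio, for the inverse).
#' @examples
#' raw_delta_from_ratio(0.00200520)          # 0
#' ratio_from_raw_delta(27.1)
#' @export
raw_delta_from_ratio <- function(ratio, constants = iso_constants()) {
  if (any(ratio <= 0)) stop("isotope ratio must be positive")
  (ratio / constants$ref_ratio - 1) * 1000
}

#' @rdname raw_delta_from_ratio
#' @export
ratio_from_raw_delta <- function(delta_raw, constants = iso_constants()) {
  if (any(delta_raw <= -1000)) stop("raw delta must exceed -1000 per mil")
  constants$ref_ratio * (1 + delta_raw / 1000)
}

#' Validate a SIMS pit table
#'
#' A pit table is a plain `data.frame`, one row per analysis spot, with at
#' least an `analysis` label and a `d18O_raw` or `d18O_vpdb` column.
#' Recognised columns: `analysis`, `d18O_vpdb`, `d18O_vsmow`, `error_2sd`,
#' `d18O_raw`, `date`, `relative_yield`, `dist_um`, `pit_category`,
#' `clfm_greyscale`, `oh_ratio` (an optional 16O1H/16O passthrough).
#'
#' @param df a data.frame of pit analyses.
#' @return `df`, invisibly classed as `pit_table`.
#' @export
as_pit_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"analysis" %in% names(df)) stop("pit table needs an 'analysis' column")
  if (!any(c("d18O_raw", "d18O_vpdb", "d18O_vsmow") %in% names(df))) {
    stop("pit table needs at least one delta column (d18O_raw/d18O_vsmow/d18O_vpdb)")
  }
  if ("relative_yield" %in% names(df) &&
      any(df$relative_yield <= 0, na.rm = TRUE)) {
    stop("relative_yield must be positive")
  }
  if ("dist_um" %in% names(df) && any(df$dist_um < 0, na.rm = TRUE)) {
    stop("dist_um must be non-negative")
  }
  if ("pit_category" %in% names(df)) {
    ok <- is.na(df$pit_category) | df$pit_category %in% 1:5
    if (!all(ok)) stop("pit_category must be 1..5 or NA (unknown)")
  }
  if ("error_2sd" %in% names(df) && any(df$error_2sd < 0, na.rm = TRUE)) {
    stop("error_2sd must be non-negative")
  }
  class(df) <- unique(c("pit_table", class(df)))
  df
}

#' A bracketed group of SIMS analyses
#'
#' One instrument bracket: running-standard analyses measured immediately
#' before and after a group of unknowns, plus the accepted value of the
#' standard. The canonical design is four standards on each side of 10-15
#' unknowns; departures are accepted with a warning.
#'
#' @param pre_standards,post_standards raw delta values of the bracketing
#'   standard analyses (per mil, raw scale).
#' @param samples a pit table ([as_pit_table()]) of unknowns with a
#'   `d18O_raw` column.
#' @param standard_true_vsmow accepted delta-18O of the running standard,
#'   per mil VSMOW (default: the UWC-3 calcite value, 12.49).
#' @return An object of class `bracket_group`.
#' @export
bracket_group <- function(pre_standards, post_standards, samples,
                          standard_true_vsmow = 12.49) {
  samples <- as_pit_table(as.data.frame(samples))
  if (!"d18O_raw" %in% names(samples)) {
    stop("bracket samples need a d18O_raw column")
  }
  n_std <- length(pre_standards) + length(post_standards)
  if (n_std == 0) stop("a bracket group needs at least one standard analysis")
  if (n_std < 2) stop("at least two standard analyses are required")
  if (n_std != 8) {
    warning("non-canonical bracket: ", n_std,
            " standards (canonical design uses 4 + 4)")
  }
  n_s <- nrow(samples)
  if (n_s < 10 || n_s > 15) {
    warning("non-canonical bracket: ", n_s,
            " samples (canonical design groups 10-15)")
  }
  structure(
    list(pre_standards = as.numeric(pre_standards),
         post_standards = as.numeric(post_standards),
         samples = samples,
         standard_true_vsmow = standard_true_vsmow),
    class = "bracket_group"
  )
}

#' Bracket-standard correction of raw SIMS deltas
#'
#' Applies the standard-bracketing reduction: the additive correction is
#' the accepted standard value minus the mean raw delta of the bracketing
#' standards, and the spot-to-spot precision attached to every unknown in
#' the group is twice the standard deviation of those bracketing standard
#' analyses.
#'
#' The correction is affine, so re-bracketing already-corrected data
#' against a standard set that averages its accepted value is the identity.
#' Standards are treated as drift-free within a bracket (bracket means, no
#' time interpolation).
#'
#' @param group a [bracket_group()].
#' @return The group's sample table with columns `d18O_vsmow` (corrected,
#'   still on the calcite-standardised instrumental scale; see
#'   [apply_polymorph_bias()]) and `error_2sd` added or replaced.
#' @export
bracket_correct <- function(group) {
  stopifnot(inherits(group, "bracket_group"))
  stds <- c(group$pre_standards, group$post_standards)
  correction <- group$standard_true_vsmow - mean(stds)
  out <- group$samples
  out$d18O_vsmow <- out$d18O_raw + correction
  out$error_2sd <- rep(if (length(stds) > 1) 2 * stats::sd(stds) else 0,
                       nrow(out))
  attr(out, "bracket_correction") <- correction
  as_pit_table(out)
}

#' Correct calcite-standardised deltas to the aragonite scale
#'
#' SIMS instrumental bias is matrix dependent: aragonite unknowns measured
#' against a calcite running standard carry a session-specific offset. The
#' bias is defined so that
#' `d18O_vsmow(aragonite scale) = d18O_vsmow(calcite-standardised) - bias`,
#' matching the reduction of the reference datasets in which a printed
#' bias of e.g. 0.61 per mil appears in the tables as "corrected to
#' aragonite (-0.61)".
#'
#' @param samples a pit table with `d18O_vsmow` and, when `bias` is a named
#'   vector, a `date` column identifying each analysis session.
#' @param bias a single bias (per mil) applied to all rows, or a named
#'   vector of per-session biases keyed by the values of `samples$date`.
#'   Absolute biases above 5 per mil are rejected as implausible.
#' @param constants constant set from [iso_constants()].
#' @return The pit table with `d18O_vsmow` shifted to the aragonite scale
#'   and `d18O_vpdb` (re)computed by the exact scale conversion.
#' @export
apply_polymorph_bias <- function(samples, bias,
                                 constants = iso_constants()) {
  samples <- as_pit_table(as.data.frame(samples))
  if (!"d18O_vsmow" %in% names(samples)) {
    stop("apply bracket_correct() first: no d18O_vsmow column")
  }
  if (any(abs(bias) >= 5)) stop("implausible polymorph bias (|bias| >= 5)")
  if (length(bias) == 1L && is.null(names(bias))) {
    b <- rep(as.numeric(bias), nrow(samples))
  } else {
    if (!"date" %in% names(samples)) {
      stop("per-session bias needs a 'date' column in the pit table")
    }
    miss <- setdiff(unique(as.character(samples$date)), names(bias))
    if (length(miss)) {
      stop("no bias supplied for session(s): ", paste(miss, collapse = ", "))
    }
    b <- as.numeric(bias[as.character(samples$date)])
  }
  samples$d18O_vsmow <- samples$d18O_vsmow - b
  samples$d18O_vpdb <- (samples$d18O_vsmow - constants$vpdb_offset) /
    constants$vpdb_slope
  as_pit_table(samples)
}

#' Estimate a session bias from paired pit populations
#'
#' When no aragonite standard was measured in a session, the
#' calcite-aragonite bias can be estimated by comparing the mean corrected
#' deltas of two user-paired populations of very closely spaced analyses
#' on the same shell, one from the session lacking a standard and one from
#' a session with a known bias.
#'
#' @param unknown_session,reference_session numeric vectors of corrected
#'   delta-18O from paired pit groups.
#' @return The difference of means (unknown minus reference), per mil: the
#'   additional bias to assign to the unknown session.
#' @export
session_bias_estimate <- function(unknown_session, reference_session) {
  if (!length(unknown_session) || !length(reference_session)) {
    stop("both pit groups must be non-empty")
  }
  mean(unknown_session) - mean(reference_session)
}

#' Relative-yield quality filter
#'
#' Keeps analyses whose secondary ion yield, relative to the mean yield of
#' the bracketing standards, strictly exceeds the threshold. Low relative
#' yield flags irreproducible analyses (typically pits intersecting
#' cavities or cracks).
#'
#' @param samples a pit table with a `relative_yield` column (percent).
#' @param threshold percent; default 95.
#' @return A list with elements `kept`, `rejected` (pit tables) and `log`,
#'   a data.frame of rejected analyses with reasons.
#' @export
yield_filter <- function(samples, threshold = 95) {
  samples <- as_pit_table(as.data.frame(samples))
  if (!"relative_yield" %in% names(samples)) {
    stop("no relative_yield column")
  }
  keep <- samples$relative_yield > threshold
  keep[is.na(keep)] <- FALSE
  log <- data.frame(
    analysis = samples$analysis[!keep],
    reason = sprintf("relative yield %.2f%% <= %.2f%%",
                     samples$relative_yield[!keep], threshold),
    stringsAsFactors = FALSE
  )
  list(kept = samples[keep, , drop = FALSE],
       rejected = samples[!keep, , drop = FALSE],
       log = log)
}

#' Pit-category quality filter
#'
#' Pit categories grade how much an analysis pit intersects cavities left
#' by removed organic matter (1 = none ... 5 = severe), assigned by SEM
#' inspection and supplied as a column. Only low-intersection categories
#' (by default 1 and 2) are considered reliable.
#'
#' @param samples a pit table with a `pit_category` column.
#' @param keep integer categories to retain.
#' @param unknown `"drop"` (default, with a warning when present) or
#'   `"keep"` for rows with `NA` category.
#' @return A list with `kept`, `rejected` and `log` as in [yield_filter()].
#' @export
category_filter <- function(samples, keep = c(1, 2),
                            unknown = c("drop", "keep")) {
  unknown <- match.arg(unknown)
  samples <- as_pit_table(as.data.frame(samples))
  if (!"pit_category" %in% names(samples)) stop("no pit_category column")
  is_na <- is.na(samples$pit_category)
  if (any(is_na) && unknown == "drop") {
    warning(sum(is_na), " pit(s) with unknown category dropped")
  }
  keep_row <- samples$pit_category %in% keep
  if (unknown == "keep") keep_row <- keep_row | is_na
  log <- data.frame(
    analysis = samples$analysis[!keep_row],
    reason = ifelse(is.na(samples$pit_category[!keep_row]),
                    "unknown pit category",
                    sprintf("pit category %d not in {%s}",
                            samples$pit_category[!keep_row],
                            paste(keep, collapse = ","))),
    stringsAsFactors = FALSE
  )
  list(kept = samples[keep_row, , drop = FALSE],
       rejected = samples[!keep_row, , drop = FALSE],
       log = log)
}

#' Per-category summaries and one-way ANOVA diagnostic
#'
#' Summarises the corrected delta-18O by pit category and, when at least
#' two categories have two or more members, adds a one-way ANOVA of delta
#' on category as a diagnostic of cavity-related contamination (cavities
#' carry isotopically light material, so increasing intersection pulls
#' measured deltas down). The ANOVA is a diagnostic, never a gate.
#'
#' @param samples a pit table with `pit_category` and a delta column.
#' @param value name of the delta column to summarise (default
#'   `"d18O_vpdb"`).
#' @return A list with `by_category` (data.frame: category, n, mean, sd)
#'   and `anova` (data.frame with F and p, or `NULL` with a message when
#'   degenerate).
#' @export
category_stats <- function(samples, value = "d18O_vpdb") {
  samples <- as_pit_table(as.data.frame(samples))
  if (!value %in% names(samples)) stop("no column ", value)
  if (!"pit_category" %in% names(samples)) stop("no pit_category column")
  df <- samples[!is.na(samples$pit_category), , drop = FALSE]
  g <- factor(df$pit_category, levels = sort(unique(df$pit_category)))
  v <- df[[value]]
  by_cat <- data.frame(
    category = as.integer(levels(g)),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(v, g, mean)),
    sd = as.numeric(tapply(v, g, stats::sd))
  )
  usable <- by_cat$n >= 2
  if (nlevels(g) >= 2 && sum(usable) >= 2) {
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    anova_df <- data.frame(F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
  } else {
    anova_df <- NULL
    message("ANOVA omitted: fewer than two categories with >= 2 members")
  }
  list(by_category = by_cat, anova = anova_df)
}
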