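## Readers/writers for the pipeline's table and config formats, the
## bundled reference fixtures, and the end-to-end driver.

# header aliases tolerated on input (lower-cased, punctuation stripped)
.pit_aliases <- list(
  analysis = c("analysis", "analysisname", "name", "id"),
  d18O_vpdb = c("d18ovpdb", "d18o_vpdb", "vpdb", "delta18ovpdb"),
  d18O_vsmow = c("d18ovsmow", "d18o_vsmow", "vsmow", "delta18ovsmow"),
  error_2sd = c("error2sd", "error_2sd", "error", "err2sd", "precision2sd"),
  d18O_raw = c("d18oraw", "d18o_raw", "raw", "deltaraw"),
  date = c("date", "session", "sessiondate"),
  relative_yield = c("relativeyield", "relative_yield", "yield"),
  dist_um = c("distum", "dist_um", "dist", "distance", "distanceum"),
  pit_category = c("pitcategory", "pit_category", "category", "pitquality",
                   "quality"),
  clfm_greyscale = c("clfmgreyscale", "clfm_greyscale", "clfm",
                     "clfmgrayscale", "greyscale"),
  oh_ratio = c("ohratio", "oh_ratio", "o16h1o16", "oh")
)

.normalise_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a SIMS pit table from CSV
#'
#' Reads a comma-separated pit table (UTF-8, '.' decimal), accepting the
#' slightly different header spellings of the two bundled reference
#' tables, and returns a typed [as_pit_table()]. Rows whose numeric
#' fields fail to parse are rejected with a line-numbered log (attribute
#' `rejected_rows`); a missing required column is a schema error naming
#' the column.
#'
#' @param path CSV file path.
#' @param expected_n optional expected row count; a mismatch is flagged
#'   with a warning (e.g. when a published table states a different n
#'   than it prints).
#' @return A pit table.
#' @export
read_pit_table <- function(path, expected_n = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character"),
    error = function(e) stop("schema error: unreadable pit table (",
                             conditionMessage(e), ")"))
  if (!nrow(raw) || !ncol(raw)) stop("schema error: empty pit table")
  norm <- .normalise_header(names(raw))
  out <- list()
  for (canon in names(.pit_aliases)) {
    hit <- which(norm %in% .pit_aliases[[canon]])
    if (length(hit)) out[[canon]] <- raw[[hit[1]]]
  }
  if (is.null(out$analysis)) stop("schema error: missing column 'analysis'")
  if (is.null(out$d18O_raw) && is.null(out$d18O_vpdb) &&
      is.null(out$d18O_vsmow)) {
    stop("schema error: missing column 'd18O_raw' (or any delta column)")
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  num_cols <- setdiff(names(df), c("analysis", "date"))
  bad <- rep(FALSE, nrow(df))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- bad | (!is.na(df[[cn]]) & nzchar(df[[cn]]) & is.na(v))
    df[[cn]] <- v
  }
  rejected <- data.frame(line = which(bad) + 1L,
                         analysis = df$analysis[bad])
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable numerics rejected (see ",
            "attr(, 'rejected_rows'))")
    df <- df[!bad, , drop = FALSE]
  }
  if ("pit_category" %in% names(df)) {
    df$pit_category <- as.integer(df$pit_category)
  }
  if (!is.null(expected_n) && nrow(df) != expected_n) {
    warning("pit table has ", nrow(df), " rows; expected ", expected_n)
  }
  df <- as_pit_table(df)
  attr(df, "rejected_rows") <- rejected
  df
}

#' @rdname read_pit_table
#' @param x a pit table.
#' @export
write_pit_table <- function(x, path) {
  stopifnot(inherits(x, "pit_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled reference SIMS tables
#'
#' The two quality-controlled SIMS analysis tables shipped with the
#' package: `"wild"` is the wild-caught *Nautilus macromphalus* transect
#' (215 of the 219 published regular analyses; four rows were lost in the
#' source-text extraction and the reader flags the count), `"aquarium"`
#' the aquarium-reared *Nautilus belauensis* (28 printed rows).
#'
#' @param which `"wild"` or `"aquarium"`.
#' @return A pit table.
#' @export
nautilus_pits <- function(which = c("wild", "aquarium")) {
  which <- match.arg(which)
  f <- switch(which,
              wild = "sims_macromphalus_wild.csv",
              aquarium = "sims_belauensis_aquarium.csv")
  n <- switch(which, wild = 219, aquarium = 28)
  path <- system.file("extdata", f, package = "bandchron", mustWork = TRUE)
  suppressWarnings(read_pit_table(path, expected_n = n))
}

#' Read a grayscale band image
#'
#' Reads a PNG or TIFF into a numeric matrix on the 0-255 grayscale used
#' by [profile_from_image()]. Multi-channel images are reduced to their
#' first (green for true-colour confocal exports belongs in channel 2;
#' pass `channel` explicitly in that case).
#'
#' @param path image file (.png, .tif/.tiff).
#' @param channel channel index for multi-channel images.
#' @return A numeric matrix, 0-255.
#' @export
read_band_image <- function(path, channel = 1L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , channel]
  img * 255
}

#' @rdname read_band_image
#' @param raster numeric matrix 0-255.
#' @export
write_band_image <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(raster / 255, 0), 1)
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read/write luminance profiles, band sets and trajectories as CSV
#'
#' Plain-CSV persistence for the intermediate artefacts: profiles
#' (`distance_um`, `brightness`, optional `residual`), band boundaries
#' (`boundary_um`), and depth trajectories (`time_h`, `depth_m`).
#'
#' @param path CSV path.
#' @param p,b,traj objects to write.
#' @param angle_deg band inclination used when reading a band set.
#' @name profile_io
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("distance_um", "brightness") %in% names(df))) {
    stop("schema error: profile CSV needs distance_um and brightness")
  }
  luminance_profile(df$distance_um, df$brightness, residual = df$residual)
}

#' @rdname profile_io
#' @export
write_profile <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @export
read_band_set <- function(path, angle_deg = 11) {
  df <- utils::read.csv(path)
  if (!"boundary_um" %in% names(df)) {
    stop("schema error: band CSV needs a boundary_um column")
  }
  band_set(df$boundary_um, angle_deg = angle_deg)
}

#' @rdname profile_io
#' @export
write_band_set <- function(b, path) {
  utils::write.csv(data.frame(boundary_um = b$boundaries), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "depth_m") %in% names(df))) {
    stop("schema error: trajectory CSV needs time_h and depth_m")
  }
  depth_trajectory(df$time_h, df$depth_m)
}

#' @rdname profile_io
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Supported top-level keys: `calibration` (overrides for
#' [iso_constants()]), `column` (`surface_temp`, `gradient`, `delta_sw`,
#' `max_depth`), `qc` (`yield_threshold`, `keep_categories`,
#' `precision_threshold`), `chronology` (`band_angle_deg`, `lowess_span`,
#' `prominence`, `hours_per_band`), `bias_by_session` (named per-session
#' biases), `paths` (`pits`, `bands`, `profile`, `trajectory`), and
#' `seed`. Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return A named list of class `pipeline_config` with defaults filled.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a named list with the keys above.
#' @export
as_pipeline_config <- function(cfg = list()) {
  known <- c("calibration", "column", "qc", "chronology",
             "bias_by_session", "paths", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  col_args <- cfg$column %||% list()
  if (is.null(col_args$surface_temp)) col_args$surface_temp <- 27.6
  qc <- utils::modifyList(list(yield_threshold = 95,
                               keep_categories = c(1, 2),
                               precision_threshold = 0.6),
                          cfg$qc %||% list())
  chron <- utils::modifyList(list(band_angle_deg = 11, lowess_span = NULL,
                                  prominence = NULL, hours_per_band = 24),
                             cfg$chronology %||% list())
  structure(list(
    constants = iso_constants(cfg$calibration %||% list()),
    column = do.call(water_column, col_args),
    qc = qc, chronology = chron,
    bias_by_session = cfg$bias_by_session,
    paths = cfg$paths %||% list(),
    seed = cfg$seed %||% 1L
  ), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full inference pipeline
#'
#' Composes the stages in analysis order: load pits, (optionally) reduce
#' raw values through bracket and polymorph corrections, apply yield and
#' category quality control, segment bands and build the band clock when
#' a profile or band file is supplied, then compute transect statistics,
#' within-band ranges, the temperature/depth envelope and the
#' fluorescence diagnostic. When no band information is available the
#' pipeline runs in no-chronology mode (transect statistics only) and
#' says so in the bundle.
#'
#' Deterministic given the config: the config seed is set at entry.
#'
#' @param config a `pipeline_config` (see [as_pipeline_config()]), or a
#'   bare list coerced through it.
#' @param pits optional pit table (overrides `paths$pits`).
#' @param bands optional [band_set()] (overrides `paths$bands`).
#' @param profile optional [luminance_profile()] (overrides
#'   `paths$profile`); used to segment bands when `bands` is absent.
#' @return A report bundle (list) with elements `pits`, `qc_log`,
#'   `bands`, `chronology`, `band_summary`, `transect`, `envelope`,
#'   `correlation`, `summary` and `mode`.
#' @export
run_pipeline <- function(config = as_pipeline_config(), pits = NULL,
                         bands = NULL, profile = NULL) {
  if (!inherits(config, "pipeline_config")) {
    config <- as_pipeline_config(config)
  }
  set.seed(config$seed)
  if (is.null(pits)) {
    if (is.null(config$paths$pits)) stop("stage load: no pit table supplied")
    pits <- read_pit_table(config$paths$pits)
  }
  pits <- as_pit_table(as.data.frame(pits))

  # calibration stage: only when raw values have not been reduced yet
  if (!"d18O_vpdb" %in% names(pits) && "d18O_vsmow" %in% names(pits)) {
    pits$d18O_vpdb <- as.numeric(vsmow_to_vpdb(
      delta18O(pits$d18O_vsmow, "VSMOW", "aragonite"), config$constants))
  }
  if (!"d18O_vpdb" %in% names(pits)) {
    stop("stage calibrate: pit table has only raw deltas; reduce brackets ",
         "first (bracket_correct/apply_polymorph_bias)")
  }

  qc_log <- list()
  if ("relative_yield" %in% names(pits)) {
    yf <- yield_filter(pits, config$qc$yield_threshold)
    qc_log$yield <- yf$log
    pits <- yf$kept
  }
  if ("pit_category" %in% names(pits)) {
    cf <- suppressWarnings(category_filter(pits, config$qc$keep_categories))
    qc_log$category <- cf$log
    pits <- cf$kept
  }
  if (!nrow(pits)) stop("stage qc: no pits survive quality control")

  if (is.null(bands) && !is.null(config$paths$bands)) {
    bands <- read_band_set(config$paths$bands,
                           angle_deg = config$chronology$band_angle_deg)
  }
  if (is.null(bands)) {
    if (is.null(profile) && !is.null(config$paths$profile)) {
      profile <- read_profile(config$paths$profile)
    }
    if (!is.null(profile)) {
      if (is.null(profile$residual)) {
        profile <- detrend_profile(profile,
                                   span_fraction = config$chronology$lowess_span)
      }
      bands <- segment_bands(profile,
                             prominence = config$chronology$prominence,
                             angle_deg = config$chronology$band_angle_deg)
    }
  }

  have_bands <- !is.null(bands) && n_bands(bands) > 0
  band_summary <- NULL
  chron <- NULL
  if (have_bands) {
    chron <- build_chronology(bands,
                              hours_per_band = config$chronology$hours_per_band)
    asg <- assign_pits_to_bands(pits, bands)
    band_summary <- within_band_ranges(
      asg$assigned, precision_threshold = config$qc$precision_threshold)
  }

  tr <- transect_range(pits)
  env <- envelope(pits, config$column, constants = config$constants)
  corr <- if ("clfm_greyscale" %in% names(pits) && nrow(pits) >= 3) {
    fluorescence_correlation(pits)
  } else NULL

  summary <- list(
    n_pits = nrow(pits),
    mode = if (have_bands) "chronology" else "no-chronology",
    delta_range = tr$range, delta_min = tr$min, delta_max = tr$max,
    temp_span = env$temp_span, depth_extent_m = env$depth_extent_m,
    n_bands = if (have_bands) n_bands(bands) else 0L,
    n_bands_exceeding = if (!is.null(band_summary)) {
      band_summary$aggregate$n_exceeding
    } else NA_integer_
  )
  structure(list(pits = pits, qc_log = qc_log, bands = bands,
                 chronology = chron, band_summary = band_summary,
                 transect = tr, envelope = env, correlation = corr,
                 summary = summary, mode = summary$mode),
            class = "pipeline_bundle")
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_bundle>", s$mode, "mode\n")
  cat(sprintf("  pits: %d  | delta range: %.2f permil (%.1f to %.1f VPDB)\n",
              s$n_pits, s$delta_range, s$delta_min, s$delta_max))
  cat(sprintf("  temperature span: %.1f degC | depth extent: %.0f m\n",
              s$temp_span, s$depth_extent_m))
  if (s$n_bands > 0) {
    cat(sprintf("  bands: %d | bands beyond precision: %s\n", s$n_bands,
                s$n_bands_exceeding))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits stable-column-order CSVs for tabular stages (pits, per-band
#' summary, QC log) and a JSON summary; decimal formatting is
#' locale-independent (C locale, '.' decimal).
#'
#' @param bundle a bundle from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "pits.csv")
  write_pit_table(bundle$pits, p)
  paths <- c(paths, p)
  if (!is.null(bundle$band_summary)) {
    p <- file.path(dir, "band_summary.csv")
    utils::write.csv(bundle$band_summary$per_band, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(bundle$qc_log)) {
    if (nrow(bundle$qc_log[[nm]])) {
      p <- file.path(dir, paste0("rejected_", nm, ".csv"))
      utils::write.csv(bundle$qc_log[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(bundle$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
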