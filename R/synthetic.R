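#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the synthetic world in one validated list. The
#' defaults emulate the wild-specimen study conditions: daily bands of
#' mean width 34.7 um with coefficient of variation 0.25 (lognormal, so
#' widths stay positive), banding inclined 11 degrees to the exterior
#' surface, SIMS analytical noise of 0.3 per mil (2SD), pit categories
#' drawn with the observed wild frequencies, contamination bias growing
#' with cavity intersection (0, 0, -0.3, -0.8, -2.0 per mil for C1..C5),
#' and a linear water column with a 0.03 degC/m gradient and seawater
#' delta-18O of 0.5 per mil VSMOW.
#'
#' @param seed integer seed; identical configs generate identical data.
#' @param n_bands number of daily bands (45, one traverse's worth).
#' @param band_width_mean_um,band_width_cv lognormal width distribution.
#' @param band_angle_deg banding inclination to the exterior surface.
#' @param band_amplitude peak-to-trough band brightness, grayscale units.
#' @param base_brightness mean brightness, grayscale units.
#' @param trend_coef polynomial coefficients (intercept first) of the slow
#'   brightness trend over normalised distance.
#' @param profile_noise_sd per-point noise of extracted profiles
#'   (grayscale units, after line averaging).
#' @param pixel_noise_sd per-pixel raster noise (grayscale units).
#' @param step_um profile sampling step.
#' @param trajectory_kind `"sinusoidal"`, `"dawn_dusk_excursion"` or
#'   `"random_walk"`.
#' @param depth_mean,depth_amplitude sinusoid parameters, metres.
#' @param excursion_depth_m,excursion_duration_h dawn/dusk excursion shape.
#' @param traj_step_h trajectory sampling step, hours.
#' @param column a [water_column()].
#' @param sims_noise_2sd analytical precision, per mil 2SD.
#' @param standard_sd per-analysis scatter of bracketing standards (per
#'   mil, 1SD); 0.15 reproduces the 0.3 per mil 2SD spot-to-spot precision.
#' @param instrument_offset raw-scale offset the bracket correction must
#'   undo, per mil.
#' @param polymorph_bias calcite-aragonite session bias, per mil.
#' @param category_probs probabilities of pit categories 1..5.
#' @param category_bias_permil contamination bias added per category.
#' @param yield_fail_frac fraction of pits drawn below the 95% yield
#'   threshold.
#' @param pit_spacing_um along-transect spacing of synthetic pits.
#' @param spot_diameter_um SIMS spot diameter.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_bands = 45,
                       band_width_mean_um = 34.7,
                       band_width_cv = 0.25,
                       band_angle_deg = 11,
                       band_amplitude = 20,
                       base_brightness = 128,
                       trend_coef = c(0, 15, -10),
                       profile_noise_sd = 2,
                       pixel_noise_sd = 8,
                       step_um = 0.25,
                       trajectory_kind = c("sinusoidal",
                                           "dawn_dusk_excursion",
                                           "random_walk"),
                       depth_mean = 150,
                       depth_amplitude = 100,
                       excursion_depth_m = 350,
                       excursion_duration_h = 3,
                       traj_step_h = 0.25,
                       column = water_column(27.6),
                       sims_noise_2sd = 0.3,
                       standard_sd = 0.15,
                       instrument_offset = -3.2,
                       polymorph_bias = 0.61,
                       category_probs = c(134, 85, 52, 14, 8) / 293,
                       category_bias_permil = c(0, 0, -0.3, -0.8, -2.0),
                       yield_fail_frac = 0.05,
                       pit_spacing_um = 12,
                       spot_diameter_um = 10) {
  trajectory_kind <- match.arg(trajectory_kind)
  stopifnot(inherits(column, "water_column"),
            length(category_probs) == 5,
            length(category_bias_permil) == 5,
            band_width_mean_um > 0, band_width_cv > 0,
            sims_noise_2sd >= 0, yield_fail_frac >= 0, yield_fail_frac < 1)
  if (abs(sum(category_probs) - 1) > 1e-8) {
    stop("category probabilities must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# lognormal draws with a given mean and coefficient of variation
.rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# global band-phase function: phi = k - 1 + fraction through band k,
# extended beyond both ends at the mean band width
.band_phase <- function(d, boundaries, mean_width) {
  k <- findInterval(d, boundaries)
  phi <- numeric(length(d))
  inside <- k >= 1 & k < length(boundaries)
  w <- diff(boundaries)
  phi[inside] <- (k[inside] - 1) +
    (d[inside] - boundaries[k[inside]]) / w[k[inside]]
  lo <- k < 1
  phi[lo] <- (d[lo] - boundaries[1]) / mean_width
  hi <- k >= length(boundaries)
  phi[hi] <- (length(boundaries) - 1) +
    (d[hi] - boundaries[length(boundaries)]) / mean_width
  phi
}

#' Generate a synthetic banded luminance profile with ground truth
#'
#' Band boundaries are laid down with lognormal widths; brightness is one
#' dark-light-dark cosine cycle per band (minima exactly at the true
#' boundaries), plus a slow polynomial trend and Gaussian point noise.
#' The profile extends a bit more than half a band beyond the outermost
#' boundaries so that every true boundary is an interior minimum.
#'
#' @param cfg a [sim_config()].
#' @return A list: `profile` (a [luminance_profile()]), `truth` (list with
#'   `boundaries`, `widths`, and the ground-truth [band_set()]).
#' @export
gen_band_profile <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  margin <- 0.6 * cfg$band_width_mean_um
  if (cfg$n_bands == 0) {
    widths <- numeric(0)
    boundaries <- numeric(0)
    d <- seq(0, 2 * margin, by = cfg$step_um)
    band_signal <- 0
  } else {
    widths <- .rlnorm_mean_cv(cfg$n_bands, cfg$band_width_mean_um,
                              cfg$band_width_cv)
    boundaries <- margin + c(0, cumsum(widths))
    d <- seq(0, max(boundaries) + margin, by = cfg$step_um)
    phi <- .band_phase(d, boundaries, cfg$band_width_mean_um)
    band_signal <- cfg$band_amplitude * 0.5 * (1 - cos(2 * pi * phi))
  }
  x01 <- (d - min(d)) / diff(range(d))
  trend <- drop(outer(x01, seq_along(cfg$trend_coef) - 1, `^`) %*%
                  cfg$trend_coef)
  noise <- stats::rnorm(length(d), 0, cfg$profile_noise_sd)
  p <- luminance_profile(d, cfg$base_brightness + band_signal + trend + noise)
  list(profile = p,
       truth = list(boundaries = boundaries, widths = widths,
                    bands = band_set(boundaries,
                                     angle_deg = cfg$band_angle_deg)))
}

#' Generate a synthetic banded grayscale raster with ground truth
#'
#' Renders the same one-cycle-per-band template as [gen_band_profile()]
#' into a 2-D image with the band lines inclined at
#' `band_angle_in_image` to the image column axis, plus per-pixel noise.
#' Useful for exercising [profile_from_image()] end to end.
#'
#' @param cfg a [sim_config()].
#' @param nrow_px,ncol_px raster size in pixels.
#' @param px_per_um image scale.
#' @param band_angle_in_image in-image band angle, degrees.
#' @return A list: `raster` (matrix), `truth` (band `widths` in um, the
#'   in-image `angle`, and `template`, the 1-D brightness function of
#'   perpendicular distance in um).
#' @export
gen_band_raster <- function(cfg, nrow_px = 200, ncol_px = 600,
                            px_per_um = 9, band_angle_in_image = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_need <- ceiling(ncol_px / px_per_um / cfg$band_width_mean_um) + 4
  widths <- .rlnorm_mean_cv(n_need, cfg$band_width_mean_um,
                            cfg$band_width_cv)
  boundaries <- c(0, cumsum(widths))
  template <- function(d_um) {
    phi <- .band_phase(d_um, boundaries, cfg$band_width_mean_um)
    cfg$base_brightness + cfg$band_amplitude * 0.5 * (1 - cos(2 * pi * phi))
  }
  th <- band_angle_in_image * pi / 180
  cc <- matrix(rep(seq_len(ncol_px), each = nrow_px), nrow = nrow_px)
  rr <- matrix(rep(seq_len(nrow_px), times = ncol_px), nrow = nrow_px)
  # perpendicular coordinate, zeroed on pixel (1,1)
  d_px <- (cc - 1) * cos(th) - (rr - 1) * sin(th)
  raster <- template(d_px / px_per_um) +
    stats::rnorm(length(d_px), 0, cfg$pixel_noise_sd)
  raster <- matrix(raster, nrow = nrow_px)
  list(raster = raster,
       truth = list(widths = widths, boundaries = boundaries,
                    angle = band_angle_in_image, template = template))
}

#' Generate a synthetic depth trajectory
#'
#' Three archetypes of diel behaviour: a regular shallow-deep sinusoid
#' with a 24 h period, a flat baseline punctuated by short square
#' excursions to depth at dawn (06:00) and dusk (18:00), or a reflected
#' Gaussian random walk. Depths are clipped to the column and flagged.
#'
#' @param cfg a [sim_config()].
#' @param duration_h total duration (default `n_bands` days).
#' @return A [depth_trajectory()]; attribute `clipped` marks clipped
#'   samples.
#' @export
gen_trajectory <- function(cfg, duration_h = cfg$n_bands * 24) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  t <- seq(0, duration_h, by = cfg$traj_step_h)
  z <- switch(cfg$trajectory_kind,
    sinusoidal = cfg$depth_mean +
      cfg$depth_amplitude * sin(2 * pi * t / 24),
    dawn_dusk_excursion = {
      tod <- t %% 24
      base <- rep(cfg$depth_mean, length(t))
      half <- cfg$excursion_duration_h / 2
      hit <- (tod >= 6 - half & tod < 6 + half) |
        (tod >= 18 - half & tod < 18 + half)
      base[hit] <- cfg$excursion_depth_m
      base
    },
    random_walk = {
      step_sd <- 15 * sqrt(cfg$traj_step_h)
      raw <- cfg$depth_mean + cumsum(stats::rnorm(length(t), 0, step_sd))
      # reflect into [0, max_depth]
      m <- cfg$column$max_depth
      raw <- abs(raw)
      raw <- m - abs(m - (raw %% (2 * m)))
      raw
    })
  clipped <- z < 0 | z > cfg$column$max_depth
  if (any(clipped)) {
    warning(sum(clipped), " trajectory point(s) clipped to the column")
  }
  z <- pmin(pmax(z, 0), cfg$column$max_depth)
  traj <- depth_trajectory(t, z)
  attr(traj, "clipped") <- clipped
  traj
}

#' Generate a bracketed synthetic SIMS dataset with full ground truth
#'
#' Emulates the measurement layer on top of a predicted isotope series:
#' pits are placed at a fixed spacing along the banded transect, read the
#' spot-averaged series at their band-clock times, acquire a
#' category-dependent contamination bias and Gaussian analytical noise,
#' and are embedded in canonical brackets (four standards either side of
#' groups of up to 12 unknowns) whose raw offset the bracket correction
#' must undo.
#'
#' @param cfg a [sim_config()].
#' @param chron a `chronology` covering the transect.
#' @param series a smeared series from [spot_average()] (or any data.frame
#'   with `time_h` and `smeared_delta`).
#' @return A list: `brackets` (list of [bracket_group()]), `pits` (the raw
#'   pit table, one row per unknown), and `truth` (per-pit true smeared
#'   delta, category, bias, and the bracket `instrument_offset`).
#' @export
gen_sims_dataset <- function(cfg, chron, series) {
  stopifnot(inherits(cfg, "sim_config"), inherits(chron, "chronology"))
  if (!"smeared_delta" %in% names(series)) {
    stop("series must carry a smeared_delta column (see spot_average)")
  }
  set.seed(cfg$seed)
  const <- iso_constants()
  b <- chron$boundaries
  dist <- seq(min(b), max(b) - 1e-9, by = cfg$pit_spacing_um)
  t_pit <- hours_at_distance(chron, dist)
  t_pit <- pmin(pmax(t_pit, min(series$time_h)), max(series$time_h))
  true_sm <- stats::approx(series$time_h, series$smeared_delta,
                           xout = t_pit)$y
  n <- length(dist)
  category <- sample(1:5, n, replace = TRUE, prob = cfg$category_probs)
  bias_cat <- cfg$category_bias_permil[category]
  noise <- stats::rnorm(n, 0, cfg$sims_noise_2sd / 2)
  vpdb_meas <- true_sm + bias_cat + noise
  vsmow_arag <- const$vpdb_slope * vpdb_meas + const$vpdb_offset
  # instrument view: calcite-standardised scale, then the raw offset
  raw <- vsmow_arag + cfg$polymorph_bias + cfg$instrument_offset
  n_fail <- stats::rbinom(1, n, cfg$yield_fail_frac)
  fail_idx <- if (n_fail > 0) sample(n, n_fail) else integer(0)
  yield <- stats::runif(n, 95.05, 99.5)
  yield[fail_idx] <- stats::runif(n_fail, 90, 95)
  pits <- as_pit_table(data.frame(
    analysis = sprintf("sim-%d", seq_len(n)),
    d18O_raw = raw,
    date = "sim",
    relative_yield = yield,
    dist_um = dist,
    pit_category = category,
    clfm_greyscale = stats::rnorm(n, 0, 3),
    stringsAsFactors = FALSE
  ))
  groups <- split(seq_len(n), ceiling(seq_len(n) / 12))
  brackets <- lapply(groups, function(ix) {
    std <- 12.49 + cfg$instrument_offset +
      stats::rnorm(8, 0, cfg$standard_sd)
    suppressWarnings(bracket_group(std[1:4], std[5:8],
                                   pits[ix, , drop = FALSE]))
  })
  list(brackets = brackets, pits = pits,
       truth = list(time_h = t_pit, true_smeared = true_sm,
                    category = category, category_bias = bias_cat,
                    instrument_offset = cfg$instrument_offset,
                    polymorph_bias = cfg$polymorph_bias))
}

#' Reduce a list of bracket groups to a corrected pit table
#'
#' Applies [bracket_correct()] to each group, binds the results, and
#' corrects to the aragonite scale via [apply_polymorph_bias()].
#'
#' @param brackets a list of [bracket_group()] objects.
#' @param bias session bias (scalar or named by `date`).
#' @param constants constant set from [iso_constants()].
#' @return A corrected pit table with `d18O_vsmow` and `d18O_vpdb`.
#' @export
reduce_brackets <- function(brackets, bias, constants = iso_constants()) {
  corrected <- lapply(brackets, bracket_correct)
  tab <- do.call(rbind, c(corrected, list(make.row.names = FALSE)))
  apply_polymorph_bias(as_pit_table(tab), bias, constants)
}
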