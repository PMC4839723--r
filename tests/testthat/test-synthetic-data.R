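# The generator must emit ground truth sufficient to score every stage.

test_that("identical seeds generate identical datasets", {
  a <- gen_band_profile(sim_config(seed = 13))
  b <- gen_band_profile(sim_config(seed = 13))
  expect_identical(a$profile$brightness, b$profile$brightness)
  expect_identical(a$truth$boundaries, b$truth$boundaries)
  ta <- gen_trajectory(sim_config(seed = 13, trajectory_kind = "random_walk"))
  tb <- gen_trajectory(sim_config(seed = 13, trajectory_kind = "random_walk"))
  expect_identical(ta$depth_m, tb$depth_m)
})

test_that("noise-free profiles are segmented to the true boundaries", {
  g <- gen_band_profile(sim_config(seed = 3, profile_noise_sd = 0,
                                   trend_coef = 0))
  b <- segment_bands(detrend_profile(g$profile))
  expect_equal(n_bands(b), length(g$truth$widths))
  expect_lt(max(abs(b$boundaries - g$truth$boundaries)), 1.5)
  # degenerate case: zero bands means a flat profile
  g0 <- gen_band_profile(sim_config(seed = 3, n_bands = 0,
                                    profile_noise_sd = 0, trend_coef = 0))
  expect_equal(diff(range(g0$profile$brightness)), 0)
})

test_that("band widths follow the configured lognormal distribution", {
  cfg <- sim_config(seed = 5, n_bands = 4000)
  g <- gen_band_profile(cfg)
  w <- g$truth$widths
  expect_true(all(w > 0))
  expect_equal(mean(w), 34.7, tolerance = 0.02)
  expect_equal(sd(w) / mean(w), 0.25, tolerance = 0.05)
})

test_that("synthetic rasters expose the same banding to the image-profile path", {
  cfg <- sim_config(seed = 2, pixel_noise_sd = 0)
  gr <- gen_band_raster(cfg, nrow_px = 120, ncol_px = 1200, px_per_um = 2,
                        band_angle_in_image = 0)
  p <- profile_from_image(gr$raster, 0, line_length_px = 100, px_per_um = 2)
  b <- segment_bands(detrend_profile(p))
  truth <- gr$truth$boundaries
  truth <- truth[truth > min(p$distance_um) + 1 & truth < max(p$distance_um) - 1]
  expect_equal(n_bands(b) + 1, length(truth))
  shift <- b$boundaries[1] - truth[1]
  expect_lt(abs(shift), 1)
  expect_lt(max(abs(b$boundaries - shift - truth)), 2)
  # inclined banding still yields plausible widths
  gr2 <- gen_band_raster(cfg, nrow_px = 120, ncol_px = 1200, px_per_um = 2,
                         band_angle_in_image = 15)
  p2 <- profile_from_image(gr2$raster, 15, line_length_px = 100, px_per_um = 2)
  b2 <- segment_bands(detrend_profile(p2))
  expect_gt(n_bands(b2), 5)
  expect_equal(mean(b2$widths), 34.7, tolerance = 0.15)
})

test_that("trajectory archetypes honour their construction", {
  flat <- gen_trajectory(sim_config(seed = 1, depth_amplitude = 0),
                         duration_h = 48)
  expect_equal(diff(range(flat$depth_m)), 0)
  dd <- gen_trajectory(sim_config(seed = 1,
                                  trajectory_kind = "dawn_dusk_excursion",
                                  depth_mean = 100, excursion_depth_m = 300,
                                  excursion_duration_h = 3),
                       duration_h = 48)
  expect_setequal(unique(dd$depth_m), c(100, 300))
  # each day spends 6 h at excursion depth (two 3-h excursions)
  day1 <- dd$time_h < 24
  frac <- mean(dd$depth_m[day1] == 300)
  expect_equal(frac, 6 / 24, tolerance = 0.05)
  rw <- gen_trajectory(sim_config(seed = 6, trajectory_kind = "random_walk"))
  expect_true(all(rw$depth_m >= 0 & rw$depth_m <= 750))
})

test_that("a noise-free measurement layer is recovered exactly by the reduction chain", {
  cfg <- sim_config(seed = 10, n_bands = 12, sims_noise_2sd = 0,
                    standard_sd = 0, yield_fail_frac = 0,
                    category_probs = c(1, 0, 0, 0, 0))
  g <- gen_band_profile(cfg)
  chron <- build_chronology(g$truth$bands)
  traj <- gen_trajectory(cfg, duration_h = max(chron$band_edges_hours))
  ser <- spot_average(delta_series(traj, cfg$column), 7)
  ds <- gen_sims_dataset(cfg, chron, ser)
  red <- reduce_brackets(ds$brackets, cfg$polymorph_bias)
  expect_equal(red$d18O_vpdb, ds$truth$true_smeared, tolerance = 1e-9)
  expect_equal(red$error_2sd, rep(0, nrow(red)))
})

test_that("the measurement layer injects recoverable category bias and yield failures", {
  cfg <- sim_config(seed = 20, n_bands = 400, pit_spacing_um = 6,
                    trajectory_kind = "sinusoidal")
  g <- gen_band_profile(cfg)
  chron <- build_chronology(g$truth$bands)
  traj <- gen_trajectory(cfg, duration_h = max(chron$band_edges_hours))
  ser <- spot_average(delta_series(traj, cfg$column), 7)
  ds <- gen_sims_dataset(cfg, chron, ser)
  red <- reduce_brackets(ds$brackets, cfg$polymorph_bias)
  # bracket correction undoes the instrument offset: residual vs truth is
  # category bias + analytical noise
  resid <- red$d18O_vpdb - ds$truth$true_smeared
  by_cat <- as.numeric(tapply(resid, red$pit_category, mean))
  expect_equal(by_cat, cfg$category_bias_permil, tolerance = 0.1)
  # yield failures hit the configured binomial rate
  n <- nrow(red)
  n_fail <- sum(red$relative_yield <= 95)
  expect_lt(abs(n_fail - n * 0.05), 3 * sqrt(n * 0.05 * 0.95))
  # category frequencies follow the configured probabilities
  counts <- tabulate(red$pit_category, 5)
  expect_equal(counts / n, cfg$category_probs, tolerance = 0.05)
})
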