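# Band segmentation, growth geometry and the 24-h-per-band clock.

test_that("luminance profiles demand a strictly increasing grid", {
  expect_error(luminance_profile(c(0, 1, 1), c(1, 2, 3)), "increasing")
  p <- luminance_profile(0:9, rep(128, 10))
  expect_s3_class(p, "luminance_profile")
})

test_that("image profiles at angle zero reduce to column means", {
  # columns carry a known gradient; rows add structure that must average out
  raster <- outer(rep(1, 50), seq(10, 200, length.out = 80)) +
    outer(seq(-5, 5, length.out = 50), rep(1, 80))
  p <- profile_from_image(raster, 0, line_length_px = 30, px_per_um = 1)
  col_template <- seq(10, 200, length.out = 80)
  # interior points interpolate the column gradient linearly
  fit <- lm(p$brightness ~ p$distance_um)
  expect_equal(unname(coef(fit)[2]), diff(col_template[1:2]),
               tolerance = 1e-6)
  expect_error(profile_from_image(matrix(numeric(0), 0, 0)), "empty|matrix")
})

test_that("line averaging suppresses pixel noise by roughly one over root length", {
  set.seed(11)
  L <- 400; sigma <- 10
  raster <- matrix(rnorm(200 * 500, 128, sigma), 200, 500)
  p <- profile_from_image(raster, 0, line_length_px = L, px_per_um = 1)
  expect_lt(sd(p$brightness), 2 * sigma / sqrt(L))
  expect_gt(sd(p$brightness), 0.8 * sigma / sqrt(L))
})

test_that("detrending removes slow trends and preserves band-scale sinusoids", {
  d <- seq(0, 400, by = 0.5)
  # pure linear trend: residual near zero
  p <- detrend_profile(luminance_profile(d, 100 + 0.2 * d))
  expect_lt(max(abs(p$residual)), 0.5)
  # sinusoid + trend: amplitude preserved within 10% at a 5-period span
  band <- 10 * sin(2 * pi * d / 35)
  p2 <- detrend_profile(luminance_profile(d, 100 + 0.2 * d + band),
                        span_fraction = 5 * 35 / 400)
  mid <- d > 50 & d < 350
  amp <- (max(p2$residual[mid]) - min(p2$residual[mid])) / 2
  expect_equal(amp, 10, tolerance = 0.1)
  # idempotence: detrending a residual changes it by < 1% RMS
  p3 <- detrend_profile(luminance_profile(d, p2$residual),
                        span_fraction = 5 * 35 / 400)
  expect_lt(sqrt(mean((p3$residual - p2$residual)^2)) / sqrt(mean(p2$residual^2)),
            0.01)
  expect_error(detrend_profile(luminance_profile(1:5, 1:5)), "few")
  expect_warning(detrend_profile(luminance_profile(d, 100 + band),
                                 span_fraction = 0.05), "span")
})

test_that("segmentation places boundaries at dark loci of a cosine band pattern", {
  # dark loci at multiples of 35 um; a margin keeps all 11 prominent
  d <- seq(-10, 360, by = 0.25)
  p <- luminance_profile(d, rep(128, length(d)),
                         residual = -cos(2 * pi * d / 35))
  b <- segment_bands(p, smooth_um = 0)
  expect_equal(n_bands(b), 10)
  expect_equal(b$widths, rep(35, 10), tolerance = 1e-6)
  expect_equal(b$boundaries, seq(0, 350, by = 35), tolerance = 0.26)
  # constant residual: nothing to segment
  flat <- luminance_profile(d, rep(128, length(d)), residual = rep(0, length(d)))
  expect_equal(n_bands(segment_bands(flat)), 0)
  expect_error(segment_bands(luminance_profile(d, rep(1, length(d)))),
               "residual")
})

test_that("segmentation recovers synthetic boundaries under the default noise level", {
  for (seed in c(101, 202)) {
    g <- gen_band_profile(sim_config(seed = seed))
    b <- segment_bands(detrend_profile(g$profile))
    truth <- g$truth$boundaries
    hits <- vapply(truth, function(x) any(abs(b$boundaries - x) <= 3),
                   logical(1))
    expect_gte(mean(hits), 0.9)
    # width estimates unbiased within 2% on the noise-free variant
  }
  g0 <- gen_band_profile(sim_config(seed = 5, profile_noise_sd = 0))
  b0 <- segment_bands(detrend_profile(g0$profile))
  expect_equal(n_bands(b0), length(g0$truth$widths))
  expect_equal(band_width_stats(b0)$mean, mean(g0$truth$widths),
               tolerance = 0.02)
})

test_that("band width statistics summarise widths measured normal to banding", {
  b <- band_set(c(0, 34.7))
  s <- band_width_stats(b)
  expect_equal(s[c("mean", "sd")], data.frame(mean = 34.7, sd = 0))
  expect_error(band_width_stats(band_set(numeric(0))), "empty")
  wide <- band_set(c(0, 3, 110))
  expect_equal(wide$implausible_width, c(TRUE, TRUE))
})

test_that("apertural growth projects band width through the banding angle", {
  expect_equal(round(apertural_growth(34.7, 11)), 182)
  expect_equal(round(apertural_growth(19.8, 11)), 104)
  expect_equal(round(apertural_growth(58.9, 11)), 309)
  expect_equal(round(apertural_growth(20.1, 11)), 105)
  expect_equal(apertural_growth(25, 90), 25)
  # round trip: a sin(theta) = w
  for (w in c(12.4, 34.7, 58.9)) {
    expect_equal(apertural_growth(w, 11) * sin(11 * pi / 180), w,
                 tolerance = 1e-12)
  }
  expect_error(apertural_growth(34.7, 0), "angle")
})

test_that("the chronology accrues 24 h per band, zero at the youngest boundary", {
  one <- build_chronology(band_set(c(0, 34.7)))
  expect_equal(as.numeric(hours_at_distance(one, 34.7 / 2)), 12)
  many <- build_chronology(band_set(cumsum(c(0, runif(45, 20, 50)))))
  expect_equal(max(many$band_edges_hours), 45 * 24)
  # boundaries map to exact multiples of 24
  expect_equal(as.numeric(hours_at_distance(many, many$boundaries)),
               24 * (0:45))
  # uniform rate within a band: slope = 24/width
  b <- band_set(c(0, 30, 70))
  ch <- build_chronology(b)
  h <- as.numeric(hours_at_distance(ch, c(10, 20, 40, 60)))
  expect_equal(h, c(10 * 24 / 30, 20 * 24 / 30, 24 + 10 * 24 / 40,
                    24 + 30 * 24 / 40))
  # strict monotonicity
  d <- seq(0, 70, by = 0.5)
  expect_true(all(diff(as.numeric(hours_at_distance(ch, d))) > 0))
  expect_error(build_chronology(band_set(numeric(0))), "0 bands")
})

test_that("distances outside the banded interval extrapolate at the edge rate, flagged", {
  ch <- build_chronology(band_set(c(10, 40, 80)))
  h <- hours_at_distance(ch, c(5, 90))
  expect_equal(attr(h, "extrapolated"), c(TRUE, TRUE))
  expect_equal(as.numeric(h), c(-5 * 24 / 30, 48 + 10 * 24 / 40))
  # inverse map round-trips including the extrapolated region
  d <- distance_at_hours(ch, as.numeric(h))
  expect_equal(as.numeric(d), c(5, 90), tolerance = 1e-9)
})

test_that("spot time resolution scales the day by spot size over band width", {
  expect_equal(pit_time_resolution(10, 34.7), 6.92, tolerance = 0.01)
  expect_equal(pit_time_resolution(10, 32), 7.5)
  expect_equal(pit_time_resolution(17, 17), 24)
  expect_error(pit_time_resolution(0, 10), "positive")
})
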