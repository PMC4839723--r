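# Reduction of raw SIMS measurements: bracketing, bias, QC filters.

test_that("raw delta and isotope ratio convert exactly both ways", {
  expect_equal(raw_delta_from_ratio(0.00200520), 0)
  expect_equal(ratio_from_raw_delta(27.1), 0.00200520 * 1.0271,
               tolerance = 1e-12)
  for (d in c(-3, 0, 12.49, 27.1)) {
    expect_equal(raw_delta_from_ratio(ratio_from_raw_delta(d)), d,
                 tolerance = 1e-10)
  }
  # linear in the ratio
  r <- c(0.00199, 0.00201, 0.00203)
  expect_equal(diff(raw_delta_from_ratio(r), differences = 2), 0,
               tolerance = 1e-9)
  expect_error(raw_delta_from_ratio(-1), "positive")
})

test_that("bracket correction shifts by the standard offset and attaches 2SD precision", {
  # standards reading exactly their accepted value: no shift, zero spread
  g <- flat_bracket(c(27.1, 25.0), 12.49)
  out <- bracket_correct(g)
  expect_equal(out$d18O_vsmow, c(27.1, 25.0))
  expect_equal(out$error_2sd, c(0, 0))
  # standards reading 24.00 against an accepted 12.49: shift of -11.51
  g2 <- flat_bracket(c(27.1, 25.0), 24.00)
  expect_equal(bracket_correct(g2)$d18O_vsmow, c(27.1, 25.0) - 11.51)
})

test_that("bracket precision reproduces the 0.3 permil 2SD for 0.15 permil standards", {
  set.seed(42)
  prec <- replicate(3000, {
    std <- rnorm(8, 9.3, 0.15)
    g <- suppressWarnings(bracket_group(std[1:4], std[5:8],
                                        data.frame(analysis = "a",
                                                   d18O_raw = 27)))
    bracket_correct(g)$error_2sd[1]
  })
  # E[2 s] = 2 sigma c4(8) = 0.2895 for sigma = 0.15
  expect_equal(mean(prec), 0.29, tolerance = 0.02)
})

test_that("bracket groups enforce the canonical design with warnings, not errors", {
  s <- data.frame(analysis = "a", d18O_raw = 27)
  w <- capture_warnings(bracket_group(c(12.4, 12.5), c(12.5), s))
  expect_match(w, "non-canonical", all = TRUE)
  expect_length(w, 2)  # standards count and sample count both flagged
  expect_error(bracket_group(numeric(0), numeric(0), s), "standard")
  expect_error(bracket_group(12.49, numeric(0), s), "two standard")
})

test_that("re-bracketing against an offset-free standard set is the identity", {
  g <- flat_bracket(c(27.1, 25.0, 26.3), 9.78)
  once <- bracket_correct(g)
  again <- bracket_correct(suppressWarnings(bracket_group(
    rep(12.49, 4), rep(12.49, 4),
    data.frame(analysis = once$analysis, d18O_raw = once$d18O_vsmow))))
  expect_equal(again$d18O_vsmow, once$d18O_vsmow, tolerance = 1e-12)
})

test_that("polymorph bias reproduces printed rows of both reference tables", {
  # aquarium specimen: raw 27.1, session bias 0.61 -> 29.2 VSMOW / -1.7 VPDB
  g <- flat_bracket(27.1, 12.49 - 2.71)
  out <- apply_polymorph_bias(bracket_correct(g), 0.61)
  expect_equal(out$d18O_vsmow, 29.2, tolerance = 1e-9)
  expect_equal(round(out$d18O_vpdb, 1), -1.7)
  # wild specimen, 2014 session: raw 26.9, bias 0.57 -> 30.2 VSMOW / -0.7 VPDB
  g2 <- flat_bracket(26.9, 12.49 - 3.87)
  out2 <- apply_polymorph_bias(bracket_correct(g2), 0.57)
  expect_equal(out2$d18O_vsmow, 30.2, tolerance = 1e-9)
  expect_equal(round(out2$d18O_vpdb, 1), -0.7)
})

test_that("polymorph bias is zero-safe, session-keyed, and validated", {
  g <- flat_bracket(c(27.1, 25.0), 12.49)
  out0 <- apply_polymorph_bias(bracket_correct(g), 0)
  expect_equal(out0$d18O_vsmow, c(27.1, 25.0))
  tab <- bracket_correct(g)
  tab$date <- c("s1", "s2")
  out <- apply_polymorph_bias(tab, c(s1 = 0.61, s2 = 0.81))
  expect_equal(out$d18O_vsmow, c(27.1 - 0.61, 25.0 - 0.81))
  expect_error(apply_polymorph_bias(tab, c(s1 = 0.61)), "s2")
  expect_error(apply_polymorph_bias(tab, 6), "implausible")
})

test_that("session bias can be estimated from paired pit populations", {
  expect_equal(session_bias_estimate(c(30.1, 30.3), c(29.9, 29.7)), 0.4,
               tolerance = 1e-12)
  expect_error(session_bias_estimate(numeric(0), 1), "non-empty")
})

test_that("yield filter keeps strictly above threshold and logs rejections", {
  tab <- pits_at(c(1, 2, 3), c(0, 0, 0),
                 relative_yield = c(96.6, 94.9, 95.0))
  f <- yield_filter(tab, 95)
  expect_equal(f$kept$analysis, "p1")
  expect_equal(nrow(f$rejected), 2)
  expect_match(f$log$reason[1], "94.90")
  f100 <- yield_filter(tab, 100)
  expect_equal(nrow(f100$kept), 0)
})

test_that("category filter keeps low-intersection pits and handles unknowns", {
  counts <- c(134, 85, 52, 14, 8)
  tab <- pits_at(seq_len(sum(counts)), 0,
                 pit_category = rep(1:5, counts))
  f <- category_filter(tab, keep = c(1, 2))
  expect_equal(nrow(f$kept), 219)
  expect_equal(nrow(category_filter(tab, keep = 1:5)$kept), sum(counts))
  aq <- pits_at(1:53, 0, pit_category = rep(1:4, c(25, 5, 16, 7))[1:53])
  # aquarium counts: C1+C2 = 30
  aq <- pits_at(1:53, 0, pit_category = rep(1:4, c(25, 5, 16, 7)))
  expect_equal(nrow(category_filter(aq, keep = c(1, 2))$kept), 30)
  tab$pit_category[1] <- NA
  expect_warning(f2 <- category_filter(tab), "unknown")
  expect_equal(nrow(f2$kept), 218)
  expect_equal(nrow(category_filter(tab, unknown = "keep")$kept), 219)
})

test_that("category summaries recover an injected contamination trend", {
  set.seed(7)
  bias <- c(0, 0, -0.3, -0.8, -2.0)
  cat_v <- rep(1:5, c(120, 80, 50, 30, 20))
  tab <- pits_at(seq_along(cat_v), rnorm(length(cat_v), -0.3 + bias[cat_v], 0.15),
                 pit_category = cat_v)
  cs <- category_stats(tab)
  expect_equal(cs$by_category$n, c(120, 80, 50, 30, 20))
  expect_true(all(diff(cs$by_category$mean[2:5]) < 0))
  expect_equal(cs$by_category$mean, -0.3 + bias, tolerance = 0.1)
  expect_lt(cs$anova$p, 0.001)
})

test_that("single-category input returns summaries but omits the ANOVA", {
  tab <- pits_at(1:5, c(-0.1, 0, 0.1, -0.2, 0.2), pit_category = rep(1L, 5))
  expect_message(cs <- category_stats(tab), "omitted")
  expect_null(cs$anova)
  expect_equal(cs$by_category$n, 5)
})
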