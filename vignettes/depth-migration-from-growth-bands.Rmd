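---
title: "Inferring sub-daily depth migration from oxygen isotopes in shell growth bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sub-daily depth migration from oxygen isotopes in shell growth bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandchron)
```

## The problem

*Nautilus* and other nektonic cephalopods migrate vertically through
hundreds of metres of water every day. Because the ocean cools with
depth and shell aragonite precipitates in (or near) oxygen isotope
equilibrium with ambient seawater, that movement leaves an isotopic
trace: shell grown at depth is isotopically heavier than shell grown
near the surface. Conventional drill sampling homogenises days to weeks
of growth and erases the signal. In-situ ion-microprobe (SIMS) spots of
~10 µm subsample *individual daily growth bands*, so within-band δ¹⁸O
variation becomes a behavioural record — provided three independent
pieces of machinery work together:

1. a **band chronometer** that turns a luminance image of daily banding
   into a distance→time map (24 h per dark–light–dark cycle),
2. a **calibration chain** that reduces raw SIMS ratios to δ¹⁸O of
   aragonite on the VPDB scale with honest precision and quality
   control, and
3. a **thermometer** that converts δ¹⁸O to temperature and temperature
   to depth through a water-column model.

`bandchron` implements all three, a forward model that predicts what a
SIMS transect *would* record for a given depth trajectory, and a
synthetic-data generator that ties the stages together for testing.

## The model

### Thermometry

Equilibrium fractionation between aragonite and water follows the
linear calibration (temperature $T$ in kelvin)

$$1000\,\ln\alpha_{\mathrm{aragonite-water}} = 17.88\,\frac{10^3}{T} - 31.14,
\qquad
\alpha = \frac{1000 + \delta^{18}O_{\mathrm{arg}}}{1000 + \delta^{18}O_{\mathrm{sw}}},$$

with both δ values on the VSMOW scale; carbonates are customarily
reported against VPDB, converted by
$\delta_{\mathrm{VSMOW}} = 1.03091\,\delta_{\mathrm{VPDB}} + 30.91$.
The calibration's quoted uncertainties (±0.13, ±0.46) are stored with
the constants but deliberately not propagated: the package reports
point estimates, as the source datasets do. All δ¹⁸O values carry
explicit scale and phase tags (`delta18O` objects); arithmetic across
scales without conversion is an error by design, because silent
scale-mixing is the classic failure mode of this calculation.

Depth inference uses a linear water column: surface temperature, a
constant cooling gradient, constant seawater δ¹⁸O, and a habitat floor
(default 750 m, the approximate implosion-depth limit for *Nautilus*).
**The default gradient is 0.03 °C/m.** A figure-caption value of
0.3 °C/m circulates for this system, but it is dimensionally
inconsistent with the arithmetic it accompanies: a ~12 °C span is
equated with ~400 m of depth change, which requires 0.03 °C/m, and
observed mean profiles near New Caledonia (17.5 °C over 800 m) imply
~0.022 °C/m. We follow the arithmetic; the printed value remains
available as a config override.

### SIMS reduction

Raw deltas are defined against the absolute ¹⁸O/¹⁶O of VSMOW
(0.00200520). Groups of 10–15 unknowns are bracketed by four standard
analyses on each side; the additive correction is the standard's
accepted value minus the bracket mean, and the spot-to-spot precision
attached to every unknown is twice the SD of the eight bracketing
standards (≈0.3 ‰ for standards scattering at 0.15 ‰). Standards are
treated as drift-free within a bracket — bracket means, no time
interpolation — matching how the reference datasets were reduced.

Because instrumental bias is matrix dependent, aragonite unknowns
measured against a calcite standard carry a session bias (0.57–0.81 ‰
in the reference sessions). The sign convention is fixed by the printed
tables: the corrected aragonite value is the calcite-standardised value
*minus* the session bias. For sessions without an aragonite standard,
`session_bias_estimate()` provides the difference-of-means estimator
over user-paired pit populations; the pairing itself is a scientific
judgement we do not automate.

Quality control is two-fold: a relative-yield filter (keep strictly
above 95 %) and SEM-assigned pit categories C1–C5 grading cavity
intersection (keep C1–C2 by default). Pits with unknown category are
dropped with a warning, since only SEM-classified pits were analysed in
the reference study. Cavity contamination pulls δ¹⁸O down
systematically; `category_stats()` reports per-category means and a
one-way ANOVA as a *diagnostic*, never a gate.

### Band chronometry

A band is one low–high–low fluorescence cycle. Boundaries are placed at
residual **minima** (dark loci), ties resolved to the leftmost
(youngest) position. Since no published segmentation rule exists for
these images (delineation was likely manual), the peak-based rule is our
stated choice, validated on synthetic data only:

* Slow brightness trends are removed by subtracting a lowess fit whose
  span covers five nominal band widths. The trend is fitted to a
  running mean of the brightness over one band width, which nulls the
  (nearly zero-mean) band oscillation before the smoother sees it; this
  makes detrending idempotent to ~0.1 % RMS where plain lowess leaks
  ~2 % of the band signal into the trend.
* Before minima detection the residual is smoothed over 5 µm (about a
  seventh of a band), suppressing pixel noise without displacing
  band-scale minima.
* Minima qualify at a prominence of half the robust (MAD) SD of the
  residual — scale-free, so it survives contrast differences between
  images.

Widths outside 5–100 µm are flagged as implausible but kept. Apertural
growth (the literature's unit) is `width / sin(angle)` with the banding
inclined ~11° to the exterior surface: 34.7 µm bands correspond to
~182 µm/day. The chronology assigns 24 h per band, uniform within a
band, zero at the youngest boundary; pits are matched to bands by the
half-open rule `[boundary_k, boundary_{k+1})`, so a pit exactly on a
boundary joins the older band. Stitching of multi-image mosaics is the
user's responsibility: the package accepts one pre-composited profile.

### Forward model and time averaging

A spot of diameter $d$ on shell growing at $g$ µm/day integrates
$\tau = 24\,d/g$ hours of growth (≈7 h for a 10 µm spot at 34.7 µm/day).
The forward model maps a depth trajectory through the column to an
equilibrium δ¹⁸O series and convolves it with a **boxcar** window of
length τ. Uniform weighting, not chord-length weighting of a circular
spot, is the default because the canonical worked example — a 3 h,
1 ‰ excursion seen through a 7 h window reading as $3/7 \approx 0.4$ ‰ —
is exactly the boxcar result; chord weighting is available as an
option. Windows truncated at the series ends are renormalised and
flagged. A sinusoid of period $P$ is attenuated by
$\sin(\pi\tau/P)/(\pi\tau/P)$, the closed form the tests check to 1 %.

## The synthetic world

The generator's defaults are the wild-specimen study conditions: 45
daily bands, widths lognormal with mean 34.7 µm and CV 0.25 (the
reported SD/mean of 8.6/34.7; lognormal keeps widths positive), banding
at 11°, SIMS noise 0.3 ‰ (2SD), bracketing standards scattering at
0.15 ‰, category frequencies 134/85/52/14/8 across C1–C5 and
contamination biases 0, 0, −0.3, −0.8, −2.0 ‰ (the observed
per-category mean offsets), pit categories independent of position
(irregular pits showed no association with band brightness), and a
0.03 °C/m column with seawater δ¹⁸O of 0.5 ‰. Brightness is one cosine
cycle per band (amplitude 20 grayscale units on a base of 128) plus a
slow polynomial trend and Gaussian noise (2 units per profile point
after line averaging, 8 per raster pixel) — values chosen once as
representative of averaged confocal profiles.

What it does **not** emulate: real confocal optics, the "graininess"
texture of crystal domains, growth-rate decline with ontogeny,
within-day growth-rate variation, or growth cessation at thermal
extremes. Passing the synthetic recovery tests therefore shows the
algorithms are correct under stated noise, not that real images
segment this cleanly; on real material the segmentation should always
be reviewed against the image.

## Numerical choices and degenerate inputs

* Temperatures are handled in kelvin internally, °C at every interface;
  the thermometer refuses temperatures outside (−2, 40) °C and the
  fractionation line outside (250, 350) K.
* Depths clip to `[0, max_depth]` with a `clipped` flag rather than
  erroring, because telemetry-style trajectories routinely brush the
  habitat floor.
* Zero bands → flat profile; fewer than two qualifying minima → empty
  band set; a single pit → zero transect range; constant fluorescence →
  correlation flagged `NA`; degenerate category groups → ANOVA omitted
  with a message.
* Bracket groups tolerate non-canonical designs (≠8 standards, ≠10–15
  unknowns) with warnings, and refuse fewer than two standards.
* The bundled reference tables are printed at 0.1 ‰ resolution, so the
  strongest chain check possible from them is consistency to printed
  rounding: converting the printed VSMOW column must match the printed
  VPDB column within `0.05 + 0.05/1.03091 ≈ 0.098 ‰` (output half-ulp
  plus propagated input half-ulp). `verify_table_chain()` applies
  exactly that bound, plus a bracket-coherence check on the per-row
  corrections.

## Problem sizes

The test suite validates segmentation on 45-band profiles at 0.25 µm
sampling, amplitude recovery on a 45-day sinusoidal migration sampled
by 200 pits across 20 noise realisations, and the measurement layer on
transects of a few thousand synthetic pits — sizes chosen to estimate
each statistic to well under its tolerance while keeping the whole
suite in the tens of seconds.

## Known limitations

* Band boundaries for the real specimens were never published, so the
  study's within-band exceedance counts (26/39 in one place, 27/41 in
  another — themselves mutually inconsistent) cannot be desk-checked;
  the package demonstrates those statistics on synthetic data instead.
* The bundled wild table carries 215 of the 219 published
  quality-controlled rows (four rows did not survive extraction from
  the source text); the C1 mean and the transect extremes are
  unaffected, the C2 mean sits at −0.45 ‰ against a published −0.5 ‰.
* Seasonal and depth variation of seawater δ¹⁸O (predicted range
  ~0.16 ‰ at this site) is not modelled; δ¹⁸O_sw enters as a constant.
* Alternative carbonate calibrations are supported only through the
  pluggable constants block, and acid-fractionation recalibration of
  standards reproduces 19.74 ‰ where 19.73 ‰ is printed — consistent
  with input rounding in the source, which does not state the unrounded
  input.
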