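Package: bandchron
Title: Sub-Daily Depth-Migration Inference from Oxygen Isotopes in Shell
    Growth Bands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring sub-daily depth-migration behaviour of
    shelled cephalopods from in-situ oxygen isotope measurements within
    daily growth bands. Implements aragonite-water oxygen isotope
    thermometry with VPDB/VSMOW scale handling, reduction of secondary ion
    mass spectrometry (SIMS) spot analyses by standard bracketing with
    yield and pit-quality control, growth-band segmentation and band-based
    chronologies from confocal luminance profiles, within-band and
    transect-wide isotope statistics with temperature and depth envelopes,
    and a spot time-averaging forward model that converts depth
    trajectories into predicted isotope series. A synthetic-data generator
    produces banded rasters, depth trajectories and bracketed SIMS
    datasets with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
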