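# shared helpers for building small synthetic inputs in code

# a bracket group whose standards all read exactly `std_raw`
flat_bracket <- function(sample_raw, std_raw, true_vsmow = 12.49) {
  suppressWarnings(bracket_group(
    rep(std_raw, 4), rep(std_raw, 4),
    data.frame(analysis = sprintf("p%d", seq_along(sample_raw)),
               d18O_raw = sample_raw),
    standard_true_vsmow = true_vsmow
  ))
}

# pit table with just deltas and distances
pits_at <- function(dist_um, d18O_vpdb, ...) {
  as_pit_table(data.frame(
    analysis = sprintf("p%d", seq_along(dist_um)),
    dist_um = dist_um, d18O_vpdb = d18O_vpdb, ...,
    stringsAsFactors = FALSE
  ))
}

# boxcar attenuation of a sinusoid of period P by a window tau
boxcar_attenuation <- function(tau, P) sin(pi * tau / P) / (pi * tau / P)
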