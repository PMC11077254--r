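# Worked-example fixtures: sloping sensorineural loss starting at 1 kHz,
# tinnitus matched at 4 kHz where the threshold is 50 dB HL.
fig_audiogram <- function() {
  audiogram(
    c(125, 250, 500, 1000, 2000, 3000, 4000, 6000, 8000),
    c(5, 5, 10, 20, 35, 45, 50, 60, 65)
  )
}

fig_profile <- function() {
  tinnitus_profile(4000, tll_db_hl = 60, mml_db_hl = 50,
                   ri = "positive", duration_months = 24)
}

quick_config <- function(seed = 1, duration_s = 4, ...) {
  synthesis_config(duration_s = duration_s, seed = seed, ...)
}

# Independent oracle: fraction of total signal power inside [lo, hi] Hz,
# from the raw one-shot periodogram (no windowing, no averaging).
band_power_fraction <- function(s, lo, hi) {
  n <- length(s$samples)
  X <- Mod(stats::fft(s$samples))^2
  f <- (seq_len(n) - 1) * s$sample_rate / n
  f <- pmin(f, s$sample_rate - f)
  sum(X[f >= lo & f <= hi]) / sum(X)
}

# Independent oracle: mean power density in [lo, hi] from the raw
# periodogram, in dB relative to the signal's total power per Hz of band.
band_density_db <- function(s, lo, hi) {
  n <- length(s$samples)
  X <- Mod(stats::fft(s$samples))^2
  f <- (seq_len(n) - 1) * s$sample_rate / n
  f <- pmin(f, s$sample_rate - f)
  keep <- f >= lo & f <= hi
  10 * log10((sum(X[keep]) / sum(X)) / (hi - lo))
}

# Independent oracle: mean in-band density via stats::spec.pgram,
# normalized by the estimate's own total so scale conventions drop out.
pgram_band_density_db <- function(s, lo, hi, spans = 65) {
  sp <- stats::spec.pgram(stats::ts(s$samples, frequency = s$sample_rate),
                          spans = spans, taper = 0.1, plot = FALSE,
                          detrend = FALSE)
  keep <- sp$freq >= lo & sp$freq <= hi
  df <- sp$freq[2] - sp$freq[1]
  10 * log10(mean(sp$spec[keep]) / (sum(sp$spec) * df))
}
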