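test_that("gaussian_noise is seed-deterministic with the target RMS", {
  cfg <- quick_config(seed = 42)
  s1 <- gaussian_noise(cfg)
  s2 <- gaussian_noise(cfg)
  expect_identical(s1$samples, s2$samples)
  expect_equal(length(s1$samples), round(cfg$duration_s * cfg$sample_rate))
  expect_equal(signal_rms(s1), cfg$target_rms, tolerance = 1e-12)
  expect_lt(abs(mean(s1$samples)),
            4 * cfg$target_rms / sqrt(length(s1$samples)))

  s3 <- gaussian_noise(cfg, seed = 43)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("white carrier is spectrally flat across adjacent octaves", {
  s <- gaussian_noise(quick_config(seed = 7, duration_s = 16))
  d1 <- band_density_db(s, 500, 1000)
  d2 <- band_density_db(s, 1000, 2000)
  expect_lt(abs(d1 - d2), 0.5)
})

test_that("smoothing_width maps the onset step to a clamped inverse width", {
  expect_equal(smoothing_width(40), 0.25)
  expect_equal(smoothing_width(5), 1.0)   # clamped at w_max
  expect_equal(smoothing_width(1000), 0.05) # clamped at w_min
  expect_equal(smoothing_width(0), 1.0)

  deltas <- seq(0, 200, by = 2.5)
  w <- smoothing_width(deltas)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0.05 & w <= 1.0))
})

test_that("envelope_v1 shapes the passband by the loss and confines energy", {
  a <- fig_audiogram()
  r <- loss_region(a)
  e <- envelope_v1(a, r)
  pb <- attr(e, "passband")
  expect_equal(pb, c(1000, 8000))
  expect_equal(max(e$gain_db), 0)

  w <- attr(e, "transition_octaves")
  expect_lte(envelope_gain_db(e, pb[1] * 2^(-2 * w)), -60 + 1e-9)
  expect_lte(envelope_gain_db(e, pb[2] * 2^(2 * w)), -60 + 1e-9)

  # flat loss -> flat 0 dB passband
  af <- audiogram(c(500, 1000, 2000, 4000), c(10, 50, 50, 50))
  ef <- envelope_v1(af, loss_region(af), config = synthesis_config())
  inside <- ef$frequency_hz >= 1000 & ef$frequency_hz <= 4000
  expect_true(all(abs(ef$gain_db[inside]) < 1e-9))

  # threshold weighting: more loss, more relative energy
  g_lo <- envelope_gain_db(e, 2000)
  g_hi <- envelope_gain_db(e, 8000)
  expect_lt(g_lo, g_hi)
  expect_equal(g_hi - g_lo, 65 - 35, tolerance = 1e-6)
})

test_that("envelope_v2 passband is exactly +/-10% around the pitch", {
  e <- envelope_v2(4000)
  expect_equal(attr(e, "passband"), c(3600, 4400))
  expect_equal(attr(envelope_v2(1000), "passband"), c(900, 1100))
  # geometric centre within 1% of the pitch
  pb <- attr(e, "passband")
  expect_equal(sqrt(pb[1] * pb[2]) / 4000, 1, tolerance = 0.01)
})

test_that("apply_envelope realizes the gain curve in the frequency domain", {
  s <- gaussian_noise(quick_config(seed = 3, duration_s = 2))

  identity_env <- make_envelope(c(20, 22000), c(0, 0), w = 0.05)
  out <- apply_envelope(s, identity_env)
  expect_equal(length(out$samples), length(s$samples))
  expect_lt(max(abs(out$samples - s$samples)) / max(abs(s$samples)), 0.05)

  floor_env <- make_envelope(c(100, 200), c(-60, -60), w = 0.05)
  quiet <- apply_envelope(s, floor_env)
  expect_lte(10 * log10(mean(quiet$samples^2) / mean(s$samples^2)), -60 + 0.5)

  shaped <- apply_envelope(s, envelope_v2(4000))
  expect_gte(band_power_fraction(shaped, 3400, 4600), 0.99)
})

test_that("normalize_rms hits the target or peak-limits", {
  s <- gaussian_noise(quick_config(seed = 4, duration_s = 1))
  out <- normalize_rms(s, target_rms = 0.2)
  expect_equal(signal_rms(out), 0.2, tolerance = 1e-6)

  t <- seq(0, 1, length.out = 44100)
  sine <- new_signal(10 * sin(2 * pi * 440 * t), 44100)
  limited <- normalize_rms(sine, target_rms = 0.9)
  expect_equal(max(abs(limited$samples)), 0.999, tolerance = 1e-9)
  expect_true(limited$meta$peak_limited)

  expect_error(normalize_rms(new_signal(rep(0, 100), 44100)), "all-zero")
})

test_that("study sound is deterministic, pitch-peaked and band-confined", {
  a <- fig_audiogram()
  p <- fig_profile()
  cfg <- quick_config(seed = 11, duration_s = 8)
  v3 <- synthesize_study(a, p, cfg)
  v3b <- synthesize_study(a, p, cfg)
  expect_identical(v3$samples, v3b$samples)
  expect_lte(max(abs(v3$samples)), 1)
  expect_equal(signal_rms(v3), cfg$target_rms, tolerance = 1e-6)

  rep <- spectrum_report(v3, passband_hint = c(1000, 8000))
  expect_gte(rep$peak_frequency, 3600)
  expect_lte(rep$peak_frequency, 4400)

  # energy below 500 Hz sits at least 40 dB under the passband median
  psd <- rep$psd
  pass_med <- stats::median(psd$power_db[psd$frequency_hz >= 1000 &
                                           psd$frequency_hz <= 8000])
  low_max <- max(psd$power_db[psd$frequency_hz > 10 & psd$frequency_hz < 500])
  expect_gte(pass_med - low_max, 40)

  # PSD additivity: the mix spectrum matches the sum of its parts
  e1 <- v3$meta$envelope_v1
  e2 <- v3$meta$envelope_v2
  v1 <- apply_envelope(gaussian_noise(cfg, seed = cfg$seed), e1)
  v2 <- apply_envelope(gaussian_noise(cfg, seed = cfg$seed + 1L), e2)
  gain <- 10^(cfg$emphasis_gain_db / 20)
  p_mix <- band_power_fraction(v3, 3600, 4400)
  p_sum <- (band_power_fraction(v1, 3600, 4400) * signal_rms(v1)^2 +
              band_power_fraction(v2, 3600, 4400) * gain^2 * signal_rms(v2)^2) /
    (signal_rms(v1)^2 + gain^2 * signal_rms(v2)^2)
  expect_equal(p_mix, p_sum, tolerance = 0.02)
})

test_that("a pitch outside the loss region warns but still synthesizes", {
  a <- audiogram(c(500, 1000, 2000, 4000), c(10, 20, 50, 60))
  p <- tinnitus_profile(500, 60, 50, "positive", 24)
  expect_warning(
    v3 <- synthesize_study(a, p, quick_config(duration_s = 1)),
    "outside the hearing-loss region")
  expect_true(v3$meta$pitch_outside_loss)
})

test_that("placebo sound fills only the normal-hearing range", {
  a <- fig_audiogram()
  cfg <- quick_config(seed = 12, duration_s = 8)
  pl <- synthesize_placebo(a, cfg)
  expect_equal(pl$meta$passband, c(125, 1000))
  expect_equal(signal_rms(pl), cfg$target_rms, tolerance = 1e-6)

  # essentially no energy in the loss frequencies
  expect_lt(band_power_fraction(pl, 2000, 20000), 1e-3)
  rep <- spectrum_report(pl, pl$meta$passband)
  expect_gte(rep$out_of_band_rejection, 40)

  expect_error(
    synthesize_placebo(audiogram(c(500, 1000, 2000), c(5, 10, 10))),
    "no hearing loss")
  expect_error(
    synthesize_placebo(audiogram(c(500, 1000, 2000), c(50, 55, 60))),
    "no normal-hearing range")
})
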