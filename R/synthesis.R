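#' Synthesis configuration
#'
#' Parameters shared by all stimulus generators. The 44.1 kHz sampling rate
#' matches consumer playback hardware; the digital RMS is a normalization
#' constant only (absolute presentation level is set on the playback device
#' per protocol phase).
#'
#' @param sample_rate Samples per second (default 44100).
#' @param duration_s File duration in seconds (default 60, intended for
#'   looped playback).
#' @param seed Integer master seed; carrier noises derive their own seeds
#'   from it.
#' @param target_rms Digital RMS of the normalized output, linear full
#'   scale (0 < rms < 1).
#' @param emphasis_gain_db Level of the pitch-emphasis band over the
#'   loss-envelope plateau, dB.
#' @param stopband_floor_db Envelope floor outside passbands, dB re the
#'   passband maximum.
#' @param v1_shape `"threshold"` weights the loss band by (threshold -
#'   cutoff); `"flat"` uses a flat 0 dB passband.
#' @param normal_cutoff Normal-hearing cutoff, dB HL.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(sample_rate = 44100, duration_s = 60, seed = 1L,
                             target_rms = 0.1, emphasis_gain_db = 6,
                             stopband_floor_db = -60,
                             v1_shape = c("threshold", "flat"),
                             normal_cutoff = 15) {
  v1_shape <- match.arg(v1_shape)
  stopifnot(sample_rate > 0, duration_s > 0,
            target_rms > 0, target_rms < 1, stopband_floor_db < 0)
  structure(
    list(sample_rate = sample_rate, duration_s = duration_s,
         seed = as.integer(seed), target_rms = target_rms,
         emphasis_gain_db = emphasis_gain_db,
         stopband_floor_db = stopband_floor_db,
         v1_shape = v1_shape, normal_cutoff = normal_cutoff),
    class = "synthesis_config"
  )
}

new_signal <- function(samples, sample_rate, seed = NA_integer_, meta = list()) {
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         seed = seed, meta = meta),
    class = "enrichment_signal"
  )
}

#' @export
print.enrichment_signal <- function(x, ...) {
  cat("<enrichment_signal> ", length(x$samples), " samples @ ", x$sample_rate,
      " Hz (", round(length(x$samples) / x$sample_rate, 2), " s), RMS ",
      signif(signal_rms(x), 4), "\n", sep = "")
  invisible(x)
}

#' Coerce a signal to a tibble of (time, amplitude)
#'
#' @param x An `enrichment_signal`.
#' @param ... Ignored.
#' @return A tibble with columns `time_s`, `amplitude`.
#' @export
as_tibble.enrichment_signal <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$sample_rate,
    amplitude = x$samples
  )
}

#' Root-mean-square amplitude of a signal
#'
#' @param s An `enrichment_signal`.
#' @return Linear RMS.
#' @export
signal_rms <- function(s) {
  sqrt(mean(s$samples^2))
}

#' Seeded Gaussian white-noise carrier
#'
#' Zero-mean Gaussian samples at the configured rate, scaled to the target
#' RMS. Identical (seed, config) always yields identical samples.
#'
#' @param config A [synthesis_config()].
#' @param seed Seed override; defaults to `config$seed`.
#' @return An `enrichment_signal`.
#' @export
gaussian_noise <- function(config = synthesis_config(), seed = config$seed) {
  n <- round(config$duration_s * config$sample_rate)
  x <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  x <- x * config$target_rms / sqrt(mean(x^2))
  new_signal(x, config$sample_rate, seed = as.integer(seed),
             meta = list(kind = "gaussian_noise"))
}

#' Band-edge smoothing width from the onset threshold step
#'
#' The transition width of the loss-band filter is inversely proportional
#' to the threshold step at the loss onset: an abrupt onset (large step)
#' gets a narrow transition that tracks it, a shallow onset a wide,
#' heavily smoothed one. Width is `c / delta` octaves, clamped to
#' `[w_min, w_max]`; a zero step returns `w_max`.
#'
#' @param delta Onset threshold step in dB (>= 0), see [onset_delta()].
#' @param c Proportionality constant, dB x octave.
#' @param w_min,w_max Clamp bounds in octaves.
#' @return Transition width in octaves; monotone nonincreasing in `delta`.
#' @examples
#' smoothing_width(40) # 0.25 octaves
#' @export
smoothing_width <- function(delta, c = 10, w_min = 0.05, w_max = 1.0) {
  if (any(delta < 0)) rlang::abort("delta must be nonnegative")
  w <- ifelse(delta == 0, w_max, c / delta)
  pmin(pmax(w, w_min), w_max)
}

# Build a spectral envelope from passband knots plus raised-cosine
# transitions of `w` octaves at both edges, floored at `floor_db`.
make_envelope <- function(pass_freq, pass_gain_db, w, floor_db = -60) {
  stopifnot(length(pass_freq) == length(pass_gain_db), length(pass_freq) >= 2)
  o <- order(pass_freq)
  pass_freq <- pass_freq[o]
  pass_gain_db <- pmax(pass_gain_db[o], floor_db)
  lo <- pass_freq[1]
  hi <- pass_freq[length(pass_freq)]
  # raised cosine in dB from the edge gain down to the floor over w octaves
  x <- seq(0, w, length.out = 25)[-1]
  rc <- function(edge_gain, x) floor_db + (edge_gain - floor_db) * (1 + cos(pi * x / w)) / 2
  below <- tibble::tibble(
    frequency_hz = lo * 2^(-x),
    gain_db = rc(pass_gain_db[1], x)
  )
  above <- tibble::tibble(
    frequency_hz = hi * 2^(x),
    gain_db = rc(pass_gain_db[length(pass_gain_db)], x)
  )
  far <- tibble::tibble(
    frequency_hz = c(lo * 2^(-8), hi * 2^(8)),
    gain_db = c(floor_db, floor_db)
  )
  env <- dplyr::bind_rows(
    far[1, ],
    below[order(below$frequency_hz), ],
    tibble::tibble(frequency_hz = pass_freq, gain_db = pass_gain_db),
    above,
    far[2, ]
  )
  env <- dplyr::distinct(env, .data$frequency_hz, .keep_all = TRUE)
  env <- dplyr::arrange(env, .data$frequency_hz)
  attr(env, "passband") <- c(lo, hi)
  attr(env, "transition_octaves") <- w
  attr(env, "floor_db") <- floor_db
  class(env) <- c("spectral_envelope", class(tibble::tibble()))
  env
}

#' Loss-configuration spectral envelope (sound complex v1)
#'
#' Confines the carrier to the hearing-loss frequency range. The passband
#' gain at each frequency is proportional (in dB) to the amount of loss,
#' `threshold - normal_cutoff`, normalized so the passband maximum is
#' 0 dB; band edges roll off as raised cosines whose width comes from the
#' onset smoothing rule (see [smoothing_width()]).
#'
#' @param a An [audiogram].
#' @param r Its [loss_region()].
#' @param w Transition width in octaves; defaults to
#'   `smoothing_width(onset_delta(a, r))`.
#' @param config A [synthesis_config()].
#' @return A tibble of class `spectral_envelope` (columns `frequency_hz`,
#'   `gain_db`) with attributes `passband`, `transition_octaves`,
#'   `floor_db`.
#' @export
envelope_v1 <- function(a, r = loss_region(a, config$normal_cutoff),
                        w = smoothing_width(onset_delta(a, r)),
                        config = synthesis_config()) {
  stopifnot(inherits(r, "hearing_loss_region"))
  if (r$f_start >= r$f_end) {
    rlang::abort("degenerate loss region: f_start must be below f_end")
  }
  grid <- 2^seq(log2(r$f_start), log2(r$f_end), length.out = 65)
  knots <- sort(unique(c(
    grid, a$frequency_hz[a$frequency_hz >= r$f_start & a$frequency_hz <= r$f_end]
  )))
  if (config$v1_shape == "flat") {
    gains <- rep(0, length(knots))
  } else {
    gains <- threshold_at(a, knots) - config$normal_cutoff
    gains <- gains - max(gains)
  }
  make_envelope(knots, gains, w = w, floor_db = config$stopband_floor_db)
}

#' Tinnitus-pitch emphasis envelope (sound complex v2)
#'
#' Unit passband exactly 10% below to 10% above the matched tinnitus
#' pitch, with narrow fixed raised-cosine edges.
#'
#' @param pitch_hz Tinnitus pitch in Hz.
#' @param config A [synthesis_config()].
#' @param w Fixed transition width in octaves.
#' @return A `spectral_envelope` with passband `[0.9, 1.1] * pitch_hz`.
#' @examples
#' attr(envelope_v2(4000), "passband") # 3600 4400
#' @export
envelope_v2 <- function(pitch_hz, config = synthesis_config(), w = 0.02) {
  stopifnot(pitch_hz > 0)
  lo <- 0.9 * pitch_hz
  hi <- 1.1 * pitch_hz
  knots <- 2^seq(log2(lo), log2(hi), length.out = 9)
  knots[1] <- lo # keep the band edges exact
  knots[9] <- hi
  make_envelope(knots, rep(0, 9), w = w, floor_db = config$stopband_floor_db)
}

#' Evaluate an envelope's gain at arbitrary frequencies
#'
#' Linear interpolation in (log2 frequency, dB) between knots; constant
#' (floor) beyond the outermost knots.
#'
#' @param e A `spectral_envelope`.
#' @param f Frequencies in Hz (0 allowed; mapped to the floor).
#' @return Gains in dB.
#' @export
envelope_gain_db <- function(e, f) {
  lf <- log2(pmax(f, 1e-6))
  stats::approx(log2(e$frequency_hz), e$gain_db, xout = lf, rule = 2)$y
}

#' Apply a spectral envelope to a signal
#'
#' Frequency-domain realization of the band-pass-plus-smoothing filter:
#' the signal's FFT is multiplied bin-wise by the envelope's linear gain
#' and inverse transformed. Zero phase, no ripple, exact band edges.
#'
#' @param s An `enrichment_signal`.
#' @param e A `spectral_envelope`.
#' @return A filtered `enrichment_signal` of the same length.
#' @export
apply_envelope <- function(s, e) {
  stopifnot(inherits(s, "enrichment_signal"), inherits(e, "spectral_envelope"))
  n <- length(s$samples)
  freqs <- (seq_len(n) - 1) * s$sample_rate / n
  freqs <- pmin(freqs, s$sample_rate - freqs) # mirror for negative bins
  gain <- 10^(envelope_gain_db(e, freqs) / 20)
  out <- Re(stats::fft(stats::fft(s$samples) * gain, inverse = TRUE)) / n
  new_signal(out, s$sample_rate, seed = s$seed,
             meta = c(s$meta, list(envelope_passband = attr(e, "passband"))))
}

#' Normalize a signal to a target RMS with peak limiting
#'
#' Scales to the requested RMS; if any sample would then exceed full
#' scale, rescales to peak 0.999 instead and records the achieved RMS in
#' `meta$actual_rms`.
#'
#' @param s An `enrichment_signal` (not all-zero).
#' @param target_rms Target linear RMS.
#' @return A normalized `enrichment_signal`.
#' @export
normalize_rms <- function(s, target_rms = 0.1) {
  rms <- signal_rms(s)
  if (rms == 0) rlang::abort("cannot normalize an all-zero signal")
  x <- s$samples * target_rms / rms
  peak <- max(abs(x))
  limited <- FALSE
  if (peak > 1) {
    x <- x * 0.999 / peak
    limited <- TRUE
  }
  new_signal(x, s$sample_rate, seed = s$seed,
             meta = c(s$meta, list(actual_rms = sqrt(mean(x^2)),
                                   peak_limited = limited)))
}

#' Synthesize the individualized study sound (sound complex v3)
#'
#' Two independent Gaussian carriers (seeds `seed` and `seed + 1`) are
#' shaped separately: v1 by the loss-configuration envelope, v2 by the
#' pitch-emphasis band. v2 is raised `emphasis_gain_db` above v1's
#' passband plateau and the two are mixed in mono, so the combined
#' spectrum covers the hearing-loss range with its maximum amplitude at
#' the tinnitus pitch. The mix is RMS-normalized and peak-limited.
#'
#' @param a An [audiogram].
#' @param p A [tinnitus_profile]; a pitch outside the loss region raises a
#'   warning (recorded in `meta$pitch_outside_loss`), not an error.
#' @param config A [synthesis_config()].
#' @return An `enrichment_signal`; `meta` holds both envelopes and the
#'   loss region.
#' @export
synthesize_study <- function(a, p, config = synthesis_config()) {
  r <- loss_region(a, config$normal_cutoff)
  e1 <- envelope_v1(a, r, config = config)
  e2 <- envelope_v2(p$pitch_hz, config = config)
  pitch_outside <- p$pitch_hz < r$f_start || p$pitch_hz > r$f_end
  if (pitch_outside) {
    rlang::warn("tinnitus pitch lies outside the hearing-loss region")
  }
  v1 <- apply_envelope(gaussian_noise(config, seed = config$seed), e1)
  v2 <- apply_envelope(gaussian_noise(config, seed = config$seed + 1L), e2)
  mix <- v1$samples + v2$samples * 10^(config$emphasis_gain_db / 20)
  out <- normalize_rms(new_signal(mix, config$sample_rate, seed = config$seed),
                       target_rms = config$target_rms)
  out$meta <- c(out$meta, list(
    kind = "study_v3", envelope_v1 = e1, envelope_v2 = e2,
    loss_region = r, pitch_hz = p$pitch_hz,
    pitch_outside_loss = pitch_outside,
    passband = c(attr(e1, "passband")[1], attr(e1, "passband")[2])
  ))
  out
}

#' Synthesize the placebo sound
#'
#' A single Gaussian carrier confined to the frequency range where hearing
#' is normal: flat 0 dB passband from the lowest measured frequency up to
#' the loss onset, with the narrowest (low-smoothing) transitions so no
#' energy reaches the loss frequencies.
#'
#' @param a An [audiogram] with a normal-hearing range below the loss
#'   onset; a fully normal audiogram (no loss region to avoid) is an
#'   error, as is a loss region starting at the lowest measured frequency.
#' @param config A [synthesis_config()].
#' @param w Transition width in octaves (low smoothing).
#' @return An `enrichment_signal`; `meta$passband` holds the band edges.
#' @export
synthesize_placebo <- function(a, config = synthesis_config(), w = 0.05) {
  r <- loss_region(a, config$normal_cutoff) # errors if no loss at all
  f_lo <- min(a$frequency_hz)
  if (r$f_start <= f_lo) {
    rlang::abort("no normal-hearing range below the loss onset")
  }
  knots <- 2^seq(log2(f_lo), log2(r$f_start), length.out = 17)
  e <- make_envelope(knots, rep(0, 17), w = w, floor_db = config$stopband_floor_db)
  out <- apply_envelope(gaussian_noise(config, seed = config$seed), e)
  out <- normalize_rms(out, target_rms = config$target_rms)
  out$meta <- c(out$meta, list(
    kind = "placebo", envelope = e, loss_region = r,
    passband = c(f_lo, r$f_start)
  ))
  out
}

#' Plot a spectral envelope
#'
#' @param object A `spectral_envelope`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spectral_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency_hz, .data$gain_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Gain (dB)") +
    ggplot2::theme_minimal()
}
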