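#' Welch averaged-periodogram power spectral density
#'
#' Hann-windowed overlapping segments, averaged modified periodograms.
#' Used for spectral verification of every generated stimulus.
#'
#' @param s An `enrichment_signal`.
#' @param n_seg Segment length in samples.
#' @param overlap Fractional overlap between segments.
#' @return A tibble with columns `frequency_hz`, `power_db` (one-sided
#'   PSD, dB re full-scale^2/Hz).
#' @export
welch_psd <- function(s, n_seg = 8192, overlap = 0.5) {
  x <- s$samples
  if (length(x) < n_seg) {
    rlang::abort("signal shorter than one analysis segment")
  }
  hop <- max(1L, floor(n_seg * (1 - overlap)))
  starts <- seq(1L, length(x) - n_seg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n_seg - 1)) / (n_seg - 1)) # Hann
  segs <- vapply(starts, function(i) x[i:(i + n_seg - 1L)] * win,
                 numeric(n_seg))
  ffts <- stats::mvfft(segs)
  keep <- seq_len(n_seg %/% 2 + 1L)
  p <- rowMeans(abs(ffts[keep, , drop = FALSE])^2) / (s$sample_rate * sum(win^2))
  p[2:(n_seg %/% 2)] <- 2 * p[2:(n_seg %/% 2)] # one-sided
  tibble::tibble(
    frequency_hz = (keep - 1L) * s$sample_rate / n_seg,
    power_db = 10 * log10(pmax(p, .Machine$double.xmin))
  )
}

#' Spectral verification report for a synthesized stimulus
#'
#' Estimates the PSD by Welch averaging (segment 8192, 50% overlap, Hann
#' window), locates the peak of the smoothed PSD, finds the -3 dB band
#' edges relative to the passband median, and measures out-of-band
#' rejection beyond a guard band that covers the filter transitions.
#'
#' @param s An `enrichment_signal`, at least 1 s long.
#' @param passband_hint Numeric pair (Hz): the nominal passband.
#' @param guard_octaves Guard band on each side of the hint excluded from
#'   the out-of-band measurement (covers the transition width).
#' @param n_seg,overlap Welch parameters.
#' @param smooth_bins Moving-average width (bins) for peak picking.
#' @return A list of class `spectrum_report`: `psd` (tibble),
#'   `peak_frequency`, `band_edges` (Hz pair), `out_of_band_rejection`
#'   (dB), `passband_hint`.
#' @export
spectrum_report <- function(s, passband_hint, guard_octaves = 1,
                            n_seg = 8192, overlap = 0.5, smooth_bins = 9) {
  if (length(s$samples) < s$sample_rate) {
    rlang::abort("signal must be at least 1 s long for spectral verification")
  }
  stopifnot(length(passband_hint) == 2, passband_hint[1] < passband_hint[2])
  psd <- welch_psd(s, n_seg = n_seg, overlap = overlap)
  sm <- stats::filter(psd$power_db, rep(1 / smooth_bins, smooth_bins), sides = 2)
  sm[is.na(sm)] <- -Inf
  peak_frequency <- psd$frequency_hz[which.max(sm)]

  in_pass <- psd$frequency_hz >= passband_hint[1] &
    psd$frequency_hz <= passband_hint[2]
  pass_median <- stats::median(psd$power_db[in_pass])

  search <- psd$frequency_hz >= passband_hint[1] / 2^guard_octaves &
    psd$frequency_hz <= passband_hint[2] * 2^guard_octaves
  above <- search & psd$power_db >= pass_median - 3
  band_edges <- range(psd$frequency_hz[above])

  oob <- (psd$frequency_hz < passband_hint[1] / 2^guard_octaves |
            psd$frequency_hz > passband_hint[2] * 2^guard_octaves) &
    psd$frequency_hz > 10 # skip the DC bins
  rejection <- if (any(oob)) pass_median - max(psd$power_db[oob]) else Inf

  structure(
    list(psd = psd, peak_frequency = peak_frequency,
         band_edges = band_edges, out_of_band_rejection = rejection,
         passband_hint = passband_hint),
    class = "spectrum_report"
  )
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat("<spectrum_report> peak ", round(x$peak_frequency), " Hz; -3 dB edges ",
      round(x$band_edges[1]), "-", round(x$band_edges[2]),
      " Hz; out-of-band rejection ", round(x$out_of_band_rejection, 1),
      " dB\n", sep = "")
  invisible(x)
}

#' @describeIn spectrum_report The PSD table.
#' @param x A `spectrum_report`.
#' @param ... Ignored.
#' @export
tidy.spectrum_report <- function(x, ...) {
  x$psd
}

#' @describeIn spectrum_report One-row summary of the spectral checks.
#' @export
glance.spectrum_report <- function(x, ...) {
  tibble::tibble(
    peak_frequency_hz = x$peak_frequency,
    band_edge_lo_hz = x$band_edges[1],
    band_edge_hi_hz = x$band_edges[2],
    out_of_band_rejection_db = x$out_of_band_rejection
  )
}

#' Write a spectrum report to JSON
#'
#' @param report A `spectrum_report`.
#' @param path Output path.
#' @param include_psd Also embed the full PSD table.
#' @return `path`, invisibly.
#' @export
write_spectrum_json <- function(report, path, include_psd = FALSE) {
  out <- list(
    peak_frequency_hz = report$peak_frequency,
    band_edges_hz = report$band_edges,
    out_of_band_rejection_db = report$out_of_band_rejection,
    passband_hint_hz = report$passband_hint
  )
  if (include_psd) out$psd <- report$psd
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a spectrum report
#'
#' PSD with the nominal passband shaded and the detected peak marked.
#'
#' @param object A `spectrum_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spectrum_report <- function(object, ...) {
  psd <- dplyr::filter(object$psd, .data$frequency_hz > 0)
  ggplot2::ggplot(psd, ggplot2::aes(.data$frequency_hz, .data$power_db)) +
    ggplot2::annotate("rect",
                      xmin = object$passband_hint[1], xmax = object$passband_hint[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$peak_frequency, linetype = 2) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (dB/Hz)") +
    ggplot2::theme_minimal()
}
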