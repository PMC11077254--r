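#' Construct a pure-tone audiogram
#'
#' An audiogram is a tibble of air-conduction hearing thresholds (dB HL) at
#' a set of measured frequencies for one ear (or the binaural mean). Rows
#' are sorted by frequency; duplicate frequencies are rejected.
#'
#' @param frequency_hz Measured frequencies in Hz, 125--20000.
#' @param threshold_db_hl Thresholds in dB HL, -10--120.
#' @param ear One of `"left"`, `"right"`, `"binaural-mean"`.
#' @return A tibble of class `audiogram` with columns `ear`, `frequency_hz`,
#'   `threshold_db_hl`.
#' @examples
#' a <- audiogram(c(500, 1000, 2000, 4000), c(10, 15, 50, 60))
#' threshold_at(a, 3000)
#' @export
audiogram <- function(frequency_hz, threshold_db_hl,
                      ear = c("binaural-mean", "left", "right")) {
  ear <- match.arg(ear)
  x <- tibble::tibble(
    ear = ear,
    frequency_hz = as.numeric(frequency_hz),
    threshold_db_hl = as.numeric(threshold_db_hl)
  )
  x <- dplyr::arrange(x, .data$frequency_hz)
  validate_audiogram(x)
  new_audiogram(x)
}

new_audiogram <- function(x) {
  class(x) <- c("audiogram", class(tibble::tibble()))
  x
}

validate_audiogram <- function(x) {
  if (nrow(x) < 2) {
    rlang::abort("an audiogram needs at least 2 measured points")
  }
  if (anyNA(x$frequency_hz) || anyNA(x$threshold_db_hl)) {
    rlang::abort("audiogram contains missing frequencies or thresholds")
  }
  if (any(diff(x$frequency_hz) <= 0)) {
    dup <- x$frequency_hz[which(diff(x$frequency_hz) <= 0) + 1]
    rlang::abort(paste0(
      "audiogram frequencies must be strictly increasing; duplicated: ",
      paste(unique(dup), collapse = ", "), " Hz"
    ))
  }
  bad_f <- x$frequency_hz < 125 | x$frequency_hz > 20000
  if (any(bad_f)) {
    rlang::abort(paste0(
      "frequencies outside the audiometric range 125-20000 Hz: ",
      paste(x$frequency_hz[bad_f], collapse = ", ")
    ))
  }
  bad_t <- x$threshold_db_hl < -10 | x$threshold_db_hl > 120
  if (any(bad_t)) {
    rlang::abort(paste0(
      "thresholds outside -10..120 dB HL: ",
      paste(x$threshold_db_hl[bad_t], collapse = ", ")
    ))
  }
  invisible(x)
}

#' Read an audiogram from CSV
#'
#' Expects the header `ear,frequency_hz,threshold_db_hl`, one row per
#' measured point, a single ear per file.
#'
#' @param path Path to a CSV file.
#' @return An [audiogram] tibble.
#' @export
read_audiogram <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("ear", "frequency_hz", "threshold_db_hl")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("audiogram CSV is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  f <- suppressWarnings(as.numeric(raw$frequency_hz))
  t <- suppressWarnings(as.numeric(raw$threshold_db_hl))
  bad <- which(is.na(f) | is.na(t))
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed audiogram row(s) at line ",
                        paste(bad + 1L, collapse = ", "), " of ", path))
  }
  ears <- unique(raw$ear)
  if (length(ears) != 1) {
    rlang::abort("audiogram CSV must contain a single ear")
  }
  audiogram(f, t, ear = ears)
}

#' Write an audiogram to CSV
#'
#' @param a An [audiogram].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_audiogram <- function(a, path) {
  readr::write_csv(tibble::as_tibble(a), path)
  invisible(path)
}

#' Interpolated hearing threshold at a frequency
#'
#' Returns the measured threshold at measured frequencies and interpolates
#' linearly in log2-frequency between neighbours (the audiometric
#' convention: thresholds are plotted per octave).
#'
#' @param a An [audiogram].
#' @param f Frequency (Hz), vectorized; must lie within the measured span.
#' @return Threshold(s) in dB HL.
#' @export
threshold_at <- function(a, f) {
  stopifnot(inherits(a, "audiogram"))
  lo <- min(a$frequency_hz)
  hi <- max(a$frequency_hz)
  if (any(f < lo | f > hi)) {
    rlang::abort(paste0("frequency outside the measured span [", lo, ", ", hi, "] Hz"))
  }
  stats::approx(log2(a$frequency_hz), a$threshold_db_hl, xout = log2(f))$y
}

#' Locate the hearing-loss frequency region
#'
#' The loss region spans from the lowest to the highest measured frequency
#' whose threshold exceeds `normal_cutoff` (normal hearing is <= 15 dB HL).
#' Also records the onset threshold and the threshold at the nearest
#' measured frequency with normal hearing, which together set the smoothing
#' of the synthesis band edges.
#'
#' @param a An [audiogram].
#' @param normal_cutoff Normal-hearing cutoff in dB HL (default 15).
#' @return A list of class `hearing_loss_region` with elements `f_start`,
#'   `f_end`, `onset_threshold`, `adjacent_normal_frequency`,
#'   `adjacent_normal_threshold` (the latter two `NA` when no measured
#'   frequency is normal), and `normal_cutoff`.
#' @export
loss_region <- function(a, normal_cutoff = 15) {
  stopifnot(inherits(a, "audiogram"))
  lossy <- a$threshold_db_hl > normal_cutoff
  if (!any(lossy)) {
    rlang::abort("no hearing loss: no threshold exceeds the normal cutoff")
  }
  f_start <- min(a$frequency_hz[lossy])
  f_end <- max(a$frequency_hz[lossy])
  onset_thr <- a$threshold_db_hl[a$frequency_hz == f_start]
  normal <- !lossy
  if (any(normal)) {
    cand_f <- a$frequency_hz[normal]
    d <- abs(log2(cand_f) - log2(f_start))
    # tie toward the lower frequency
    adj_f <- cand_f[order(d, cand_f)][1]
    adj_t <- a$threshold_db_hl[a$frequency_hz == adj_f]
  } else {
    adj_f <- NA_real_
    adj_t <- NA_real_
  }
  structure(
    list(
      f_start = f_start, f_end = f_end,
      onset_threshold = onset_thr,
      adjacent_normal_frequency = adj_f,
      adjacent_normal_threshold = adj_t,
      normal_cutoff = normal_cutoff
    ),
    class = "hearing_loss_region"
  )
}

#' @export
print.hearing_loss_region <- function(x, ...) {
  cat("<hearing_loss_region> ", x$f_start, "-", x$f_end, " Hz; onset ",
      x$onset_threshold, " dB HL (adjacent normal ",
      x$adjacent_normal_threshold, " dB HL @ ",
      x$adjacent_normal_frequency, " Hz)\n", sep = "")
  invisible(x)
}

#' Threshold step at the loss onset
#'
#' Absolute difference between the threshold where hearing loss starts and
#' the threshold at the nearest measured frequency with normal hearing.
#' This difference drives the band-edge smoothing: an abrupt onset gets a
#' narrow transition, a shallow onset a wide one (see [smoothing_width]).
#'
#' @param a An [audiogram].
#' @param r A [loss_region] computed from `a`.
#' @return The difference in dB (nonnegative).
#' @export
onset_delta <- function(a, r = loss_region(a)) {
  stopifnot(inherits(r, "hearing_loss_region"))
  if (is.na(r$adjacent_normal_threshold)) {
    rlang::abort("no measured frequency with a normal threshold adjacent to the loss onset")
  }
  abs(r$onset_threshold - r$adjacent_normal_threshold)
}

#' Standard audiometric frequency ladder
#'
#' @param extended Include the extended high-frequency ladder up to 20 kHz.
#' @return Frequencies in Hz.
#' @export
audiometric_ladder <- function(extended = FALSE) {
  base <- c(125, 250, 500, 1000, 2000, 3000, 4000, 6000, 8000)
  if (extended) {
    c(base, 10000, 12500, 16000, 20000)
  } else {
    base
  }
}

#' Plot an audiogram
#'
#' Conventional audiogram axes: log2 frequency, inverted dB HL.
#'
#' @param object An [audiogram].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.audiogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency_hz, .data$threshold_db_hl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 4, size = 2) +
    ggplot2::scale_x_continuous(
      trans = "log2",
      breaks = c(125, 250, 500, 1000, 2000, 4000, 8000, 16000),
      labels = c(".125", ".25", ".5", "1", "2", "4", "8", "16")
    ) +
    ggplot2::scale_y_reverse(limits = c(120, -10)) +
    ggplot2::labs(x = "Frequency (kHz)", y = "Threshold (dB HL)") +
    ggplot2::theme_minimal()
}
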