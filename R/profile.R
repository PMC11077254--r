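#' Construct a tinnitus psychoacoustic profile
#'
#' Holds the assessment outcomes used for screening and dosing: the matched
#' tinnitus pitch, tinnitus loudness level (TLL), minimum masking level
#' (MML), residual-inhibition (RI) outcome, duration and laterality.
#'
#' @param pitch_hz Matched tinnitus pitch in Hz (125--20000).
#' @param tll_db_hl Tinnitus loudness level, dB HL (0--120).
#' @param mml_db_hl Minimum masking level, dB HL (0--120).
#' @param ri RI outcome, `"positive"` or `"negative"`.
#' @param duration_months Tinnitus duration in months (>= 0).
#' @param laterality `"right"`, `"left"` or `"bilateral_or_head"`.
#' @param tonal Logical; tonal (vs noise-like) tinnitus.
#' @return A one-row tibble of class `tinnitus_profile`.
#' @examples
#' tinnitus_profile(4000, tll_db_hl = 60, mml_db_hl = 50,
#'                  ri = "positive", duration_months = 24)
#' @export
tinnitus_profile <- function(pitch_hz, tll_db_hl, mml_db_hl,
                             ri = c("positive", "negative"),
                             duration_months,
                             laterality = c("bilateral_or_head", "right", "left"),
                             tonal = TRUE) {
  ri <- match.arg(ri)
  laterality <- match.arg(laterality)
  if (pitch_hz < 125 || pitch_hz > 20000) {
    rlang::abort("tinnitus pitch must lie within 125-20000 Hz")
  }
  if (tll_db_hl < 0 || tll_db_hl > 120 || mml_db_hl < 0 || mml_db_hl > 120) {
    rlang::abort("TLL and MML must lie within 0-120 dB HL")
  }
  if (duration_months < 0) {
    rlang::abort("duration must be nonnegative")
  }
  x <- tibble::tibble(
    laterality = laterality,
    pitch_hz = as.numeric(pitch_hz),
    tll_db_hl = as.numeric(tll_db_hl),
    mml_db_hl = as.numeric(mml_db_hl),
    ri = ri,
    duration_months = as.numeric(duration_months),
    tonal = isTRUE(tonal)
  )
  class(x) <- c("tinnitus_profile", class(tibble::tibble()))
  x
}

#' Read a tinnitus profile from JSON
#'
#' @param path Path to a JSON file with fields `pitch_hz`, `tll_db_hl`,
#'   `mml_db_hl`, `ri`, `duration_months`, and optionally `laterality`,
#'   `tonal`.
#' @return A [tinnitus_profile].
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pitch_hz", "tll_db_hl", "mml_db_hl", "ri", "duration_months")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("profile JSON is missing field(s): ",
                        paste(miss, collapse = ", ")))
  }
  tinnitus_profile(
    pitch_hz = x$pitch_hz, tll_db_hl = x$tll_db_hl, mml_db_hl = x$mml_db_hl,
    ri = x$ri, duration_months = x$duration_months,
    laterality = x$laterality %||% "bilateral_or_head",
    tonal = x$tonal %||% TRUE
  )
}

#' Write a tinnitus profile to JSON
#'
#' @param p A [tinnitus_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  jsonlite::write_json(as.list(tibble::as_tibble(p)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Psychoacoustic assessment constants
#'
#' The fixed parameters of the tinnitus assessment battery: contralateral
#' pitch matching at 30 dB SL, 5 dB steps for loudness and masking
#' matches, and residual-inhibition testing with narrowband noise at
#' MML + 10 dB for 60 s.
#'
#' @return A one-row tibble with columns `pitch_match_level_db_sl`,
#'   `step_db`, `ri_level_above_mml_db`, `ri_duration_s`.
#' @export
assessment_constants <- function() {
  tibble::tibble(
    pitch_match_level_db_sl = 30,
    step_db = 5,
    ri_level_above_mml_db = 10,
    ri_duration_s = 60
  )
}

#' Level at which residual inhibition is tested
#'
#' Narrowband noise centred on the tinnitus pitch is presented at the
#' minimum masking level plus a fixed increment.
#'
#' @param p A [tinnitus_profile].
#' @param constants Assessment constants, see [assessment_constants()].
#' @return Presentation level in dB HL.
#' @export
ri_test_level <- function(p, constants = assessment_constants()) {
  p$mml_db_hl + constants$ri_level_above_mml_db
}
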