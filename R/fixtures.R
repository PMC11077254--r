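#' Specification for synthetic fixtures
#'
#' Parameters of the synthetic-data generator. Defaults emulate the
#' screened clinical population: sloping sensorineural audiograms whose
#' loss begins at 1 kHz and rises toward high frequencies, a tinnitus
#' pitch placed where the threshold sits in the 45--55 dB HL window, and a
#' cohort reproducing the printed participant flow (127 admitted: 6
#' organic, 11 pitch-threshold-out, 10 RI-negative, 4 profound, 96
#' included).
#'
#' @param loss_onset First audiometric frequency with an elevated
#'   threshold (Hz).
#' @param slope Loss slope above onset, dB/octave.
#' @param onset_level Threshold at the onset frequency, dB HL.
#' @param pitch_quantile Where along the qualifying (45--55 dB HL)
#'   frequencies the pitch is placed, as a fraction.
#' @param jitter_db Half-width of the seeded uniform threshold jitter, dB;
#'   bounded so category membership cannot flip.
#' @param seed Integer master seed.
#' @param cohort_counts Named counts per screening category:
#'   `eligible`, `organic`, `pitch_out`, `ri_negative`, `profound`.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(loss_onset = 1000, slope = 15, onset_level = 20,
                         pitch_quantile = 0.5, jitter_db = 3, seed = 1L,
                         cohort_counts = c(eligible = 96, organic = 6,
                                           pitch_out = 11, ri_negative = 10,
                                           profound = 4)) {
  stopifnot(slope >= 0, jitter_db >= 0, all(cohort_counts >= 0))
  structure(
    list(loss_onset = loss_onset, slope = slope, onset_level = onset_level,
         pitch_quantile = pitch_quantile, jitter_db = jitter_db,
         seed = as.integer(seed), cohort_counts = cohort_counts),
    class = "fixture_spec"
  )
}

#' Generate a synthetic sloping-loss audiogram
#'
#' Normal thresholds (<= 15 dB HL) below the loss onset; from the onset
#' upward the threshold starts at `onset_level` and rises at `slope`
#' dB/octave with seeded jitter, capped at 90 dB HL unless `profound`,
#' in which case the highest measured frequency is set above 90.
#'
#' @param spec A [fixture_spec()].
#' @param profound Insert one threshold above 90 dB HL.
#' @param seed Seed override; defaults to `spec$seed`.
#' @param ladder Measured frequencies (Hz).
#' @return An [audiogram].
#' @export
gen_audiogram <- function(spec = fixture_spec(), profound = FALSE,
                          seed = spec$seed, ladder = audiometric_ladder()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(as.integer(seed), {
    jit <- stats::runif(length(ladder), -spec$jitter_db, spec$jitter_db)
    thr <- ifelse(
      ladder < spec$loss_onset,
      pmin(8 + jit, 15),
      pmin(spec$onset_level + spec$slope * log2(ladder / spec$loss_onset) + jit, 90)
    )
    if (profound) {
      thr[length(thr)] <- 95 + stats::runif(1, 0, 5)
    }
  })
  audiogram(ladder, round(thr, 1))
}

#' Generate a tinnitus profile consistent with an audiogram
#'
#' Places the tinnitus pitch at a measured frequency whose threshold lies
#' in the 45--55 dB HL window (or deliberately outside it for the
#' `pitch_out` category), sets TLL a small sensation-level offset above
#' the pitch threshold and MML below TLL, and draws a chronic duration.
#' Constructed so that each screening category fails eligibility for
#' exactly its defining reason.
#'
#' @param a An [audiogram].
#' @param spec A [fixture_spec()].
#' @param category One of `"eligible"`, `"organic"`, `"pitch_out"`,
#'   `"ri_negative"`, `"profound"`.
#' @param seed Seed override.
#' @param window Qualifying threshold window at the pitch, dB HL.
#' @return A [tinnitus_profile].
#' @export
gen_profile <- function(a, spec = fixture_spec(),
                        category = c("eligible", "organic", "pitch_out",
                                     "ri_negative", "profound"),
                        seed = spec$seed, window = c(45, 55)) {
  category <- match.arg(category)
  margin <- spec$jitter_db
  if (category == "pitch_out") {
    # a lossy frequency safely outside the window even under jitter
    ok <- a$threshold_db_hl > 15 &
      (a$threshold_db_hl < window[1] - margin |
         a$threshold_db_hl > window[2] + margin) &
      a$threshold_db_hl <= 90
    if (!any(ok)) rlang::abort("no frequency with a threshold clearly outside the window")
    pitch <- a$frequency_hz[ok][1]
  } else {
    q <- a$frequency_hz[a$threshold_db_hl >= window[1] &
                          a$threshold_db_hl <= window[2]]
    if (length(q) == 0) {
      rlang::abort("audiogram has no frequency with a threshold in the qualifying window")
    }
    pitch <- q[max(1L, ceiling(spec$pitch_quantile * length(q)))]
  }
  thr <- threshold_at(a, pitch)
  withr::with_seed(as.integer(seed), {
    tll <- min(thr + sample(c(5, 10, 15), 1), 120)
    mml <- max(tll - sample(c(5, 10), 1), 0)
    duration <- sample(14:52, 1)
    lat <- sample(c("right", "left", "bilateral_or_head"), 1,
                  prob = c(0.25, 0.25, 0.5))
  })
  tinnitus_profile(
    pitch_hz = pitch, tll_db_hl = tll, mml_db_hl = mml,
    ri = if (category == "ri_negative") "negative" else "positive",
    duration_months = duration, laterality = lat, tonal = TRUE
  )
}

#' Generate a synthetic screening cohort
#'
#' Emits exactly the requested number of records per screening category,
#' shuffled under the seed. Each record's category-defining attribute is
#' the only eligibility criterion it violates, so [filter_cohort()]
#' reproduces the requested flow exactly.
#'
#' @param spec A [fixture_spec()]; `spec$cohort_counts` sets the category
#'   sizes.
#' @return A tibble with columns `id`, `category`, `organic` and
#'   list-columns `profile`, `audiogram`.
#' @examples
#' flow <- filter_cohort(gen_cohort(fixture_spec(seed = 7)))
#' glance(flow)
#' @export
gen_cohort <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  counts <- spec$cohort_counts
  categories <- rep(names(counts), times = counts)
  n <- length(categories)
  if (n == 0) {
    return(tibble::tibble(id = character(0), category = character(0),
                          organic = logical(0), profile = list(),
                          audiogram = list()))
  }
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max - 2L, 2L * n))
  records <- purrr::map(seq_len(n), function(i) {
    cat_i <- categories[i]
    a <- gen_audiogram(spec, profound = cat_i == "profound", seed = seeds[2 * i - 1])
    p <- gen_profile(a, spec, category = cat_i, seed = seeds[2 * i])
    list(category = cat_i, organic = cat_i == "organic",
         audiogram = a, profile = p)
  })
  ord <- withr::with_seed(spec$seed + 1L, sample.int(n))
  records <- records[ord]
  tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    category = purrr::map_chr(records, "category"),
    organic = purrr::map_lgl(records, "organic"),
    profile = purrr::map(records, "profile"),
    audiogram = purrr::map(records, "audiogram")
  )
}

#' Write a cohort to disk as CSV plus per-record audiogram files
#'
#' The cohort CSV holds one row per record with the profile fields inline,
#' the organic flag and a relative reference to the record's audiogram
#' CSV under `audiograms/`.
#'
#' @param cohort A cohort tibble from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return The cohort CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "audiograms"), recursive = TRUE, showWarnings = FALSE)
  files <- file.path("audiograms", paste0(cohort$id, ".csv"))
  purrr::walk2(cohort$audiogram, files,
               ~ write_audiogram(.x, file.path(dir, .y)))
  tab <- dplyr::bind_cols(
    tibble::tibble(id = cohort$id, organic = cohort$organic,
                   audiogram_file = files),
    dplyr::bind_rows(purrr::map(cohort$profile, tibble::as_tibble))
  )
  path <- file.path(dir, "cohort.csv")
  readr::write_csv(tab, path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Path to the cohort CSV; audiogram references are resolved
#'   relative to its directory.
#' @return A cohort tibble with list-columns `profile`, `audiogram`.
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  base <- dirname(path)
  tibble::tibble(
    id = tab$id,
    organic = tab$organic,
    profile = purrr::pmap(tab, function(pitch_hz, tll_db_hl, mml_db_hl, ri,
                                        duration_months, laterality, tonal, ...) {
      tinnitus_profile(pitch_hz, tll_db_hl, mml_db_hl, ri, duration_months,
                       laterality, tonal)
    }),
    audiogram = purrr::map(tab$audiogram_file,
                           ~ read_audiogram(file.path(base, .x)))
  )
}
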