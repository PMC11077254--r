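#' Exclusion reasons recognised by the screen
#'
#' In the tally precedence order used by [filter_cohort()]: organic
#' pathology, pitch-frequency threshold outside the 45--55 dB HL window,
#' negative residual inhibition, profound loss (> 90 dB HL anywhere),
#' non-chronic (<= 6 months), non-tonal, and no measurable hearing loss.
#'
#' @return Character vector of reason codes.
#' @export
exclusion_reasons <- function() {
  c("ORGANIC", "PITCH_THRESHOLD_OUT_OF_RANGE", "RI_NEGATIVE",
    "PROFOUND_LOSS", "NOT_CHRONIC", "NOT_TONAL", "NO_LOSS")
}

#' Screen a tinnitus profile for sound-enrichment eligibility
#'
#' Implements the inclusion criteria that tie the tinnitus etiology to
#' hearing loss: the hearing threshold at the matched tinnitus pitch must
#' fall in the 45--55 dB HL window (the range where, per the discordant
#' damage model, outer-hair-cell damage maximally exceeds inner-hair-cell
#' damage), residual inhibition must be positive, tinnitus must be chronic
#' (> 6 months) and tonal, no measured threshold may exceed 90 dB HL, and
#' no organic pathology may explain the tinnitus.
#'
#' @param p A [tinnitus_profile].
#' @param a The matching [audiogram]; must span the tinnitus pitch.
#' @param organic Logical flag: organic pathology identified on medical
#'   history / imaging / audiological workup.
#' @param window Closed threshold window at the pitch, dB HL.
#' @param profound_cutoff Exclusion above this threshold anywhere, dB HL
#'   (strict: 90 is retained, 91 excluded).
#' @param chronic_months Chronicity bound in months (strict: > 6 required).
#' @param normal_cutoff Normal-hearing cutoff for the loss region, dB HL.
#' @return A list of class `eligibility_result` with `eligible` (logical)
#'   and `reasons` (character vector, empty iff eligible).
#' @examples
#' a <- audiogram(c(500, 1000, 2000, 4000, 8000), c(10, 20, 35, 50, 65))
#' p <- tinnitus_profile(4000, 60, 50, "positive", 24)
#' check_eligibility(p, a)
#' @export
check_eligibility <- function(p, a, organic = FALSE,
                              window = c(45, 55),
                              profound_cutoff = 90,
                              chronic_months = 6,
                              normal_cutoff = 15) {
  stopifnot(inherits(p, "tinnitus_profile"), inherits(a, "audiogram"))
  thr_at_pitch <- threshold_at(a, p$pitch_hz) # errors if pitch outside span
  reasons <- character(0)
  if (isTRUE(organic)) reasons <- c(reasons, "ORGANIC")
  if (thr_at_pitch < window[1] || thr_at_pitch > window[2]) {
    reasons <- c(reasons, "PITCH_THRESHOLD_OUT_OF_RANGE")
  }
  if (p$ri == "negative") reasons <- c(reasons, "RI_NEGATIVE")
  if (any(a$threshold_db_hl > profound_cutoff)) {
    reasons <- c(reasons, "PROFOUND_LOSS")
  }
  if (p$duration_months <= chronic_months) reasons <- c(reasons, "NOT_CHRONIC")
  if (!p$tonal) reasons <- c(reasons, "NOT_TONAL")
  if (!any(a$threshold_db_hl > normal_cutoff)) reasons <- c(reasons, "NO_LOSS")
  structure(
    list(eligible = length(reasons) == 0, reasons = reasons),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  if (x$eligible) {
    cat("<eligibility_result> eligible\n")
  } else {
    cat("<eligibility_result> ineligible:", paste(x$reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.eligibility_result <- function(x, ...) {
  tibble::tibble(
    eligible = x$eligible,
    reason = if (x$eligible) character(0) else x$reasons
  )
}

#' Screen a cohort and tally the participant flow
#'
#' Applies [check_eligibility()] to every record and tallies exclusions by
#' the first reason triggered in precedence order (organic, then
#' pitch-threshold, RI, profound loss, chronicity, tonality, no loss), so
#' each excluded record is counted under exactly one primary reason.
#'
#' @param cohort A tibble with list-columns `profile` and `audiogram` and a
#'   logical column `organic`, one row per screened record (as produced by
#'   [gen_cohort()]).
#' @param ... Passed to [check_eligibility()].
#' @return A list of class `cohort_flow`: `admitted`, named integer vector
#'   `excluded_by_reason`, and `included`. Always satisfies
#'   `admitted == included + sum(excluded_by_reason)`.
#' @examples
#' flow <- filter_cohort(gen_cohort(fixture_spec(
#'   cohort_counts = c(eligible = 5, organic = 1, pitch_out = 1,
#'                     ri_negative = 1, profound = 1))))
#' glance(flow)
#' @export
filter_cohort <- function(cohort, ...) {
  order_reasons <- exclusion_reasons()
  excluded <- stats::setNames(integer(length(order_reasons)), order_reasons)
  included <- 0L
  n <- if (is.null(cohort) || nrow(cohort) == 0) 0L else nrow(cohort)
  if (n > 0) {
    for (i in seq_len(n)) {
      res <- check_eligibility(cohort$profile[[i]], cohort$audiogram[[i]],
                               organic = cohort$organic[i], ...)
      if (res$eligible) {
        included <- included + 1L
      } else {
        primary <- order_reasons[min(match(res$reasons, order_reasons))]
        excluded[primary] <- excluded[primary] + 1L
      }
    }
  }
  structure(
    list(admitted = n, excluded_by_reason = excluded, included = included),
    class = "cohort_flow"
  )
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("<cohort_flow> admitted ", x$admitted, " -> included ", x$included, "\n", sep = "")
  shown <- x$excluded_by_reason[x$excluded_by_reason > 0]
  if (length(shown) > 0) {
    cat("  excluded:", paste(names(shown), shown, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn filter_cohort One row per exclusion reason with its count.
#' @param x A `cohort_flow`.
#' @export
tidy.cohort_flow <- function(x, ...) {
  tibble::tibble(
    reason = names(x$excluded_by_reason),
    n_excluded = as.integer(x$excluded_by_reason)
  )
}

#' @describeIn filter_cohort One-row summary: admitted, excluded, included.
#' @export
glance.cohort_flow <- function(x, ...) {
  tibble::tibble(
    admitted = x$admitted,
    excluded = sum(x$excluded_by_reason),
    included = x$included
  )
}

#' Write a cohort-flow report to JSON
#'
#' @param flow A `cohort_flow` from [filter_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_flow_json <- function(flow, path) {
  jsonlite::write_json(
    list(
      admitted = flow$admitted,
      excluded = as.list(flow$excluded_by_reason),
      included = flow$included
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Randomly assign eligible records to study and placebo groups
#'
#' Deterministic seeded shuffle followed by a ratio split; the same seed
#' always reproduces the same assignment.
#'
#' @param eligible_ids Vector of record identifiers (nonempty).
#' @param seed Integer seed.
#' @param ratio Fraction assigned to the study group; the study arm gets
#'   `round(ratio * n)` records, the placebo arm the remainder.
#' @return A tibble of class `group_assignment` with columns `id`, `group`
#'   and attribute `seed`.
#' @export
randomize <- function(eligible_ids, seed, ratio = 0.5) {
  if (length(eligible_ids) == 0) {
    rlang::abort("cannot randomize an empty set of ids")
  }
  n <- length(eligible_ids)
  n_study <- round(ratio * n)
  shuffled <- withr::with_seed(seed, sample(eligible_ids, n))
  out <- tibble::tibble(
    id = shuffled,
    group = rep(c("study", "placebo"), times = c(n_study, n - n_study))
  )
  out <- dplyr::arrange(out, match(.data$id, eligible_ids))
  attr(out, "seed") <- seed
  class(out) <- c("group_assignment", class(tibble::tibble()))
  out
}
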