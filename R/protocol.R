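#' Build the phased sound-enrichment listening plan
#'
#' Three contiguous phases over 6 months with de-escalating dose:
#' \itemize{
#'   \item months 0--1: 6 h/day, level above the tinnitus loudness but
#'     comfortable (anchored one step above TLL; the comfort ceiling is a
#'     device-side instruction);
#'   \item months 1--3: 3 h/day, level just above the tinnitus suppression
#'     level (anchored at MML + one step);
#'   \item months 3--6: 2 h/day, level just below the tinnitus level
#'     (anchored at TLL - one step).
#' }
#' "Just above"/"just below" are quantified as one audiometric step, the
#' instrument's 5 dB minimum.
#'
#' @param p A [tinnitus_profile] with TLL and MML.
#' @param step Audiometric step in dB.
#' @return A tibble of class `protocol_plan` with columns `phase`,
#'   `start_month`, `end_month`, `daily_hours`, `level_rule`,
#'   `level_anchor_db_hl`.
#' @examples
#' build_plan(tinnitus_profile(4000, 60, 50, "positive", 24))
#' @export
build_plan <- function(p, step = 5) {
  stopifnot(inherits(p, "tinnitus_profile"))
  if (is.na(p$tll_db_hl) || is.na(p$mml_db_hl)) {
    rlang::abort("profile must carry TLL and MML to build a plan")
  }
  out <- tibble::tibble(
    phase = 1:3,
    start_month = c(0, 1, 3),
    end_month = c(1, 3, 6),
    daily_hours = c(6, 3, 2),
    level_rule = c("ABOVE_TINNITUS_COMFORTABLE", "JUST_ABOVE_SUPPRESSION",
                   "JUST_BELOW_TINNITUS"),
    level_anchor_db_hl = c(p$tll_db_hl + step, p$mml_db_hl + step,
                           p$tll_db_hl - step)
  )
  class(out) <- c("protocol_plan", class(tibble::tibble()))
  out
}

#' Write a listening plan to JSON
#'
#' @param plan A `protocol_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(tibble::as_tibble(plan), path, digits = NA)
  invisible(path)
}

#' Summarize listening adherence against the plan
#'
#' Buckets a daily usage log into protocol phases (30 days per month) and
#' reports, per phase, the mean daily listening time and the fraction of
#' logged days meeting the phase's daily target.
#'
#' @param log A data frame with columns `day` (1-based study day) and
#'   `minutes` (nonnegative listening minutes).
#' @param plan A `protocol_plan` from [build_plan()].
#' @param days_per_month Calendar convention for phase boundaries.
#' @return A tibble with one row per phase: `phase`, `target_minutes`,
#'   `n_days_logged`, `mean_daily_minutes`, `compliance`.
#' @export
adherence_summary <- function(log, plan, days_per_month = 30) {
  stopifnot(inherits(plan, "protocol_plan"))
  if (is.null(log) || nrow(log) == 0) {
    log <- tibble::tibble(day = integer(0), minutes = numeric(0))
  }
  if (any(log$minutes < 0)) {
    rlang::abort("listening minutes must be nonnegative")
  }
  phases <- dplyr::mutate(
    tibble::as_tibble(plan),
    start_day = .data$start_month * days_per_month + 1,
    end_day = .data$end_month * days_per_month,
    target_minutes = .data$daily_hours * 60
  )
  purrr::pmap_dfr(phases, function(phase, start_day, end_day, target_minutes, ...) {
    d <- dplyr::filter(log, .data$day >= start_day, .data$day <= end_day)
    tibble::tibble(
      phase = phase,
      target_minutes = target_minutes,
      n_days_logged = nrow(d),
      mean_daily_minutes = if (nrow(d) > 0) mean(d$minutes) else 0,
      compliance = if (nrow(d) > 0) mean(d$minutes >= target_minutes) else 0
    )
  })
}
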