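test_that("check_eligibility applies the screening criteria jointly", {
  a <- fig_audiogram() # 50 dB HL at 4 kHz, max threshold 65
  p <- fig_profile()   # pitch 4 kHz, RI positive, 24 months, tonal
  expect_true(check_eligibility(p, a)$eligible)

  # pitch at a frequency with 35 dB HL -> outside the 45-55 window
  p_out <- tinnitus_profile(2000, 60, 50, "positive", 24)
  res <- check_eligibility(p_out, a)
  expect_false(res$eligible)
  expect_equal(res$reasons, "PITCH_THRESHOLD_OUT_OF_RANGE")

  # one threshold above 90 dB HL
  a_prof <- audiogram(a$frequency_hz, replace(a$threshold_db_hl, 9, 95))
  res <- check_eligibility(fig_profile(), a_prof)
  expect_equal(res$reasons, "PROFOUND_LOSS")
  # the rule is strict: exactly 90 is retained
  a_edge <- audiogram(a$frequency_hz, replace(a$threshold_db_hl, 9, 90))
  expect_true(check_eligibility(fig_profile(), a_edge)$eligible)

  expect_equal(check_eligibility(
    tinnitus_profile(4000, 60, 50, "negative", 24), a)$reasons, "RI_NEGATIVE")
  expect_equal(check_eligibility(
    tinnitus_profile(4000, 60, 50, "positive", 6), a)$reasons, "NOT_CHRONIC")
  expect_equal(check_eligibility(
    tinnitus_profile(4000, 60, 50, "positive", 24, tonal = FALSE), a)$reasons,
    "NOT_TONAL")
  expect_equal(check_eligibility(fig_profile(), a, organic = TRUE)$reasons,
               "ORGANIC")

  # pitch outside the measured span is a domain error, not a reason
  expect_error(check_eligibility(
    tinnitus_profile(16000, 60, 50, "positive", 24), a), "span")
})

test_that("every ineligible record carries known reasons and eligible iff none", {
  spec <- fixture_spec(seed = 42, cohort_counts = c(
    eligible = 6, organic = 2, pitch_out = 3, ri_negative = 2, profound = 2))
  cohort <- gen_cohort(spec)
  for (i in seq_len(nrow(cohort))) {
    res <- check_eligibility(cohort$profile[[i]], cohort$audiogram[[i]],
                             organic = cohort$organic[i])
    expect_identical(res$eligible, length(res$reasons) == 0)
    expect_true(all(res$reasons %in% exclusion_reasons()))
  }
})

test_that("filter_cohort conserves counts and ignores record order", {
  spec <- fixture_spec(seed = 9, cohort_counts = c(
    eligible = 10, organic = 2, pitch_out = 3, ri_negative = 2, profound = 1))
  cohort <- gen_cohort(spec)
  flow <- filter_cohort(cohort)
  expect_equal(flow$admitted, flow$included + sum(flow$excluded_by_reason))
  expect_equal(flow$included, 10)
  expect_equal(unname(flow$excluded_by_reason[c(
    "ORGANIC", "PITCH_THRESHOLD_OUT_OF_RANGE", "RI_NEGATIVE", "PROFOUND_LOSS")]),
    c(2L, 3L, 2L, 1L))

  shuffled <- cohort[withr::with_seed(1, sample.int(nrow(cohort))), ]
  flow2 <- filter_cohort(shuffled)
  expect_identical(flow2$excluded_by_reason, flow$excluded_by_reason)
  expect_identical(flow2$included, flow$included)

  empty <- filter_cohort(cohort[0, ])
  expect_equal(empty$admitted, 0L)
  expect_equal(empty$included, 0L)
  expect_true(all(empty$excluded_by_reason == 0))

  expect_equal(glance(flow)$included, 10)
  expect_setequal(tidy(flow)$reason, exclusion_reasons())
})

test_that("multi-failure records are tallied once under the first reason", {
  a <- fig_audiogram()
  # fails both RI and chronicity; RI precedes chronicity in the tally order
  p <- tinnitus_profile(4000, 60, 50, "negative", 3)
  cohort <- tibble::tibble(id = "X", organic = FALSE,
                           profile = list(p), audiogram = list(a))
  flow <- filter_cohort(cohort)
  expect_equal(unname(flow$excluded_by_reason["RI_NEGATIVE"]), 1L)
  expect_equal(sum(flow$excluded_by_reason), 1L)
})

test_that("randomize splits deterministically by seed and ratio", {
  ids <- sprintf("P%03d", 1:96)
  g <- randomize(ids, seed = 20, ratio = 52 / 96)
  expect_equal(sum(g$group == "study"), 52)
  expect_equal(sum(g$group == "placebo"), 44)
  expect_setequal(g$id, ids)

  g2 <- randomize(ids, seed = 20, ratio = 52 / 96)
  expect_identical(g$group, g2$group)
  g3 <- randomize(ids, seed = 21, ratio = 52 / 96)
  expect_false(identical(g$group, g3$group))

  expect_true(all(randomize(ids, seed = 1, ratio = 1)$group == "study"))
  expect_error(randomize(character(0), seed = 1), "empty")
})
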