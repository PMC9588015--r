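mk_measure <- function(vaf, probe_pass = TRUE, timepoint = "T3.1", month = 11) {
  tibble::tibble(
    timepoint = timepoint, month = month,
    pos = seq_along(vaf), vaf = vaf, probe_pass = rep_len(probe_pass, length(vaf))
  )
}

test_that("positivity fires strictly above the 0.005% threshold", {
  expect_identical(call_positivity(mk_measure(c(0, 0, 7e-5))), "positive")
  expect_identical(call_positivity(mk_measure(5e-5)), "negative")
  expect_identical(call_positivity(mk_measure(5.0001e-5)), "positive")
  expect_identical(
    call_positivity(mk_measure(c(1e-3, 1e-3), probe_pass = FALSE)),
    "indeterminate"
  )
  # Failed probes are excluded even when other probes pass.
  m <- mk_measure(c(1e-3, 0))
  m$probe_pass <- c(FALSE, TRUE)
  expect_identical(call_positivity(m), "negative")
  # Requiring two positive variants changes the call.
  cfg2 <- positivity_config(min_positive_variants = 2)
  expect_identical(call_positivity(mk_measure(c(0, 0, 7e-5)), cfg2), "negative")
  expect_identical(call_positivity(mk_measure(c(6e-5, 7e-5)), cfg2), "positive")
})

test_that("positivity is monotone in the VAF threshold", {
  set.seed(59)
  for (i in 1:50) {
    m <- mk_measure(runif(4, 0, 2e-4), probe_pass = runif(4) < 0.8)
    thr <- sort(runif(2, 1e-6, 2e-4))
    hi <- call_positivity(m, positivity_config(vaf_threshold = thr[2]))
    lo <- call_positivity(m, positivity_config(vaf_threshold = thr[1]))
    if (hi == "positive") expect_identical(lo, "positive")
    expect_identical(hi == "indeterminate", lo == "indeterminate")
  }
})

test_that("patient classification follows the stated precedence", {
  base <- dplyr::bind_rows(
    mk_measure(c(3e-3, 1e-3), timepoint = "T0", month = 0),
    mk_measure(c(0, 0), timepoint = "T2", month = 5)
  )
  expect_identical(classify_patient(base, 5)$category, "evaluable")

  # No post-surgery draw.
  pre_only <- mk_measure(c(3e-3, 1e-3), timepoint = "T0", month = 0)
  expect_identical(classify_patient(pre_only, 5)$category, "insufficient_data")

  # No baseline draw.
  post_only <- mk_measure(c(0, 0), timepoint = "T2", month = 5)
  expect_identical(classify_patient(post_only, 5)$category, "insufficient_data")

  # A near-100% plasma VAF marks a germline artifact, trumping all else.
  germ <- dplyr::bind_rows(
    mk_measure(c(0.98, 1e-3), timepoint = "T0", month = 0)
  )
  expect_identical(classify_patient(germ, 5)$category, "germline_artifact")

  # Baseline below 0.05% on every variant: low baseline signal.
  low <- dplyr::bind_rows(
    mk_measure(c(3e-4, 1e-4), timepoint = "T0", month = 0),
    mk_measure(c(0, 0), timepoint = "T2", month = 5)
  )
  expect_identical(classify_patient(low, 5)$category, "low_baseline_signal")

  expect_error(classify_patient(base[0, ], 5), class = "mrdtrace_input_error")
})

test_that("molecular relapse is the earliest post-surgical positive, excluding T4", {
  data <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(0, timepoint = "T2", month = 5),
    mk_measure(2e-4, timepoint = "T3.3", month = 24),
    mk_measure(8e-4, timepoint = "T3.4", month = 30)
  )
  expect_equal(detect_molecular_relapse(data, 5), 24)

  # Positives only before surgery never trigger molecular relapse.
  pre <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(4e-3, timepoint = "T1", month = 0.1),
    mk_measure(0, timepoint = "T2", month = 5)
  )
  expect_true(is.na(detect_molecular_relapse(pre, 5)))

  # Residual disease at surgery counts as relapse at the surgery month.
  at_surgery <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(6e-4, timepoint = "T2", month = 5)
  )
  expect_equal(detect_molecular_relapse(at_surgery, 5), 5)

  # The relapse-confirmation draw is excluded.
  t4_only <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(0, timepoint = "T2", month = 5),
    mk_measure(5e-2, timepoint = "T4", month = 20)
  )
  expect_true(is.na(detect_molecular_relapse(t4_only, 5)))
})

test_that("lead times subtract molecular from clinical months with sign flagging", {
  expect_equal(compute_lead_time(24, 31), 7)
  expect_equal(compute_lead_time(12, 12), 0)
  expect_warning(lead <- compute_lead_time(12, 10), "Negative lead time")
  expect_equal(lead, -2)
})

test_that("cohort summary reports the mean detected lead time with half-up rounding", {
  mon <- dplyr::bind_rows(
    make_monitor(4,
      in_denom = TRUE, detected = TRUE, ever_positive = TRUE,
      lead = NA
    ) |>
      dplyr::mutate(lead_time_months = c(7, 3, 5, 2)),
    make_monitor(3, category = "insufficient_data") |>
      dplyr::mutate(patient_id = paste0("X", patient_id))
  )
  s <- summarize_cohort(mon)
  expect_equal(s$mean_lead_time_months, 4.3)
  expect_equal(s$n_relapse_detected, 4)
  expect_equal(s$n_relapse_eligible, 4)
  expect_equal(s$sensitivity, 1)
  expect_equal(
    s$category_counts$n[s$category_counts$category == "insufficient_data"], 3
  )
})

test_that("relapses without a recent draw leave the sensitivity denominator", {
  clinical <- tibble::tibble(
    patient_id = c("R1", "R2"), pcr = FALSE, surgery_month = 5,
    clinical_relapse_month = c(30, 30), last_followup_month = 30
  )
  near <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(0, timepoint = "T2", month = 5),
    mk_measure(4e-4, timepoint = "T3.2", month = 26)
  )
  far <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(0, timepoint = "T2", month = 5),
    mk_measure(4e-4, timepoint = "T3.2", month = 21)
  )
  m <- dplyr::bind_rows(
    dplyr::mutate(near, patient_id = "R1"),
    dplyr::mutate(far, patient_id = "R2")
  )
  tl <- assemble_timeline(m, clinical)
  mon <- monitor_cohort(tl)
  # R1's last draw is 4 months before relapse: eligible and detected.
  expect_true(mon$in_sensitivity_denominator[mon$patient_id == "R1"])
  expect_true(mon$detected[mon$patient_id == "R1"])
  # R2's last draw is 9 months before relapse: excluded from the denominator.
  expect_false(mon$in_sensitivity_denominator[mon$patient_id == "R2"])
  s <- summarize_cohort(mon)
  expect_equal(s$n_relapse_eligible, 1)
})

test_that("a relapse-free cohort has undefined sensitivity, not zero", {
  mon <- make_monitor(5, ever_positive = FALSE)
  s <- summarize_cohort(mon)
  expect_true(is.na(s$sensitivity))
  expect_null(s$sensitivity_ci)
  expect_true(is.na(s$mean_lead_time_months))
})

test_that("ever-positive flags come from remission draws only", {
  clinical <- tibble::tibble(
    patient_id = "P1", pcr = TRUE, surgery_month = 5,
    clinical_relapse_month = 20, last_followup_month = 20
  )
  m <- dplyr::bind_rows(
    mk_measure(3e-3, timepoint = "T0", month = 0),
    mk_measure(0, timepoint = "T2", month = 5),
    mk_measure(0, timepoint = "T3.1", month = 11),
    mk_measure(5e-2, timepoint = "T4", month = 20)
  ) |>
    dplyr::mutate(patient_id = "P1")
  mon <- monitor_cohort(assemble_timeline(m, clinical))
  # Positive only at baseline and the T4 relapse draw: never remission-positive.
  expect_false(mon$ever_positive_remission)
  expect_true(is.na(mon$molecular_relapse_month))
})
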