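# Molecular-relapse monitoring: the positivity rule (any panel variant
# VAF > 0.005%), patient evaluability classification, molecular-relapse
# detection over the post-surgical monitoring window, lead times, and the
# cohort-level detection summary.

#' Positivity and monitoring configuration
#'
#' @param vaf_threshold A timepoint is positive when at least
#'   `min_positive_variants` probe-passing panel variants have VAF strictly
#'   above this fraction (default 5e-5, i.e. 0.005%).
#' @param min_positive_variants Variants required above threshold
#'   (default 1, the published rule; 2 guards against single-variant false
#'   positives).
#' @param baseline_detectability_threshold Patients whose every baseline
#'   plasma VAF is below this (default 5e-4, i.e. 0.05%) are not evaluable
#'   for monitoring.
#' @param germline_vaf_flag A panel variant at or above this plasma VAF
#'   (default 0.90) at any timepoint marks an apparent germline variant.
#' @param relapse_window_months A relapse counts toward detection
#'   sensitivity only when a monitoring draw fell within this many months
#'   before the clinical relapse (default 6).
#' @return A list of class `positivity_config`.
#' @export
positivity_config <- function(vaf_threshold = 5e-5,
                              min_positive_variants = 1,
                              baseline_detectability_threshold = 5e-4,
                              germline_vaf_flag = 0.90,
                              relapse_window_months = 6) {
  check_probability(vaf_threshold, "vaf_threshold", allow_zero = FALSE, allow_one = FALSE)
  check_probability(baseline_detectability_threshold, "baseline_detectability_threshold",
    allow_zero = FALSE, allow_one = FALSE
  )
  check_probability(germline_vaf_flag, "germline_vaf_flag", allow_zero = FALSE)
  if (relapse_window_months <= 0) {
    abort("relapse_window_months must be positive.", class = "mrdtrace_config_error")
  }
  structure(
    list(
      vaf_threshold = vaf_threshold,
      min_positive_variants = check_count(min_positive_variants, "min_positive_variants"),
      baseline_detectability_threshold = baseline_detectability_threshold,
      germline_vaf_flag = germline_vaf_flag,
      relapse_window_months = relapse_window_months
    ),
    class = "positivity_config"
  )
}

#' Call ctDNA positivity for one timepoint
#'
#' Positive when at least `min_positive_variants` probe-passing variants
#' have VAF strictly above `vaf_threshold` ("VAF > 0.005%");
#' indeterminate when no probe-passing variant with a defined VAF exists.
#'
#' @param measurements One timepoint's measurements (`vaf`, `probe_pass`).
#' @param cfg A [positivity_config()].
#' @return `"positive"`, `"negative"` or `"indeterminate"`.
#' @export
call_positivity <- function(measurements, cfg = positivity_config()) {
  evaluable <- measurements$probe_pass & !is.na(measurements$vaf)
  if (!any(evaluable)) {
    return("indeterminate")
  }
  n_pos <- sum(measurements$vaf[evaluable] > cfg$vaf_threshold)
  if (n_pos >= cfg$min_positive_variants) "positive" else "negative"
}

#' Classify a patient's evaluability
#'
#' Precedence: `germline_artifact` (any panel variant at plasma VAF >=
#' `germline_vaf_flag` at any timepoint) before `insufficient_data` (no
#' baseline draw, no evaluable baseline measurement, or no draw at or
#' after surgery) before `low_baseline_signal` (every evaluable baseline
#' VAF below `baseline_detectability_threshold`) before `evaluable`.
#'
#' @param data One patient's draw-level measurements (`timepoint`,
#'   `month`, `vaf`, `probe_pass`).
#' @param surgery_month Month of surgery.
#' @param cfg A [positivity_config()].
#' @return A list with `category` and `reason`.
#' @export
classify_patient <- function(data, surgery_month, cfg = positivity_config()) {
  if (nrow(data) == 0) {
    abort("Empty timeline: cannot classify patient.", class = "mrdtrace_input_error")
  }
  defined <- !is.na(data$vaf)
  if (any(defined & data$vaf >= cfg$germline_vaf_flag)) {
    return(list(
      category = "germline_artifact",
      reason = sprintf(
        "panel variant at VAF >= %.0f%% in plasma", 100 * cfg$germline_vaf_flag
      )
    ))
  }
  baseline <- data[data$timepoint == "T0", , drop = FALSE]
  baseline_eval <- baseline[baseline$probe_pass & !is.na(baseline$vaf), , drop = FALSE]
  if (nrow(baseline) == 0) {
    return(list(category = "insufficient_data", reason = "no baseline draw"))
  }
  if (!any(data$month >= surgery_month)) {
    return(list(category = "insufficient_data", reason = "no draw at or after surgery"))
  }
  if (nrow(baseline_eval) == 0) {
    return(list(
      category = "insufficient_data",
      reason = "no evaluable baseline measurement"
    ))
  }
  if (all(baseline_eval$vaf < cfg$baseline_detectability_threshold)) {
    return(list(
      category = "low_baseline_signal",
      reason = sprintf(
        "all baseline VAFs < %s", fmt_percent(cfg$baseline_detectability_threshold, 3,
          exact_only = FALSE
        )
      )
    ))
  }
  list(category = "evaluable", reason = "baseline detectable, monitored post-surgery")
}

#' Detect molecular relapse
#'
#' The molecular-relapse month is the earliest positive monitoring
#' timepoint at or after surgery; the draw taken at clinical relapse (T4)
#' is excluded — it confirms relapse rather than predicting it. A positive
#' call at the surgery draw itself signals persistent residual disease.
#'
#' @param data One patient's draw-level measurements.
#' @param surgery_month Month of surgery.
#' @param cfg A [positivity_config()].
#' @return The molecular-relapse month, or `NA` if never positive in the
#'   monitoring window.
#' @export
detect_molecular_relapse <- function(data, surgery_month, cfg = positivity_config()) {
  calls <- positivity_by_timepoint(data, cfg)
  window <- calls[calls$month >= surgery_month & calls$timepoint != "T4", , drop = FALSE]
  pos <- window$month[window$positivity == "positive"]
  if (length(pos) == 0) NA_real_ else min(pos)
}

# Per-timepoint positivity calls for one patient's measurements.
positivity_by_timepoint <- function(data, cfg = positivity_config()) {
  data |>
    dplyr::group_by(.data$timepoint, .data$month) |>
    dplyr::summarise(
      positivity = call_positivity(dplyr::pick(dplyr::everything()), cfg),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$month)
}

#' Lead time between molecular and clinical relapse
#'
#' @param molecular_month Month of molecular relapse.
#' @param clinical_month Month of clinical relapse.
#' @return `clinical_month - molecular_month` in months; 0 when
#'   simultaneous; negative (with a warning) when the molecular call came
#'   after the clinical relapse.
#' @export
compute_lead_time <- function(molecular_month, clinical_month) {
  lead <- clinical_month - molecular_month
  if (any(!is.na(lead) & lead < 0)) {
    warn("Negative lead time: molecular relapse called after clinical relapse.")
  }
  lead
}

#' Monitor every patient in a timeline
#'
#' Applies classification, per-timepoint positivity, molecular-relapse
#' detection and lead-time computation to each patient. The
#' remission-monitoring window is `[surgery, clinical relapse)`: the
#' ever-positive flag counts only probe-evaluable monitoring draws in that
#' window (T4 relapse draws never count), and a relapsed patient enters
#' the sensitivity denominator only when a monitoring draw fell within
#' `relapse_window_months` before the clinical relapse.
#'
#' @param timeline An `mrd_timeline` from [assemble_timeline()].
#' @param cfg A [positivity_config()].
#' @return A tibble of class `mrd_monitor`: one row per patient with
#'   `category`, `molecular_relapse_month`, `lead_time_months`,
#'   `ever_positive_remission`, `in_sensitivity_denominator`, `detected`,
#'   and a `positivity` list-column of per-timepoint calls.
#' @export
monitor_cohort <- function(timeline, cfg = positivity_config()) {
  stopifnot(inherits(timeline, "mrd_timeline") || all(
    c("patient_id", "pcr", "surgery_month", "clinical_relapse_month", "data") %in%
      names(timeline)
  ))
  rows <- purrr::pmap(
    list(
      timeline$patient_id, timeline$pcr, timeline$surgery_month,
      timeline$clinical_relapse_month, timeline$last_followup_month,
      timeline$data
    ),
    function(pid, pcr, surg, relapse_m, followup_m, data) {
      cls <- classify_patient(data, surg, cfg)
      calls <- positivity_by_timepoint(data, cfg)
      evaluable <- cls$category == "evaluable"

      mol_month <- if (evaluable) detect_molecular_relapse(data, surg, cfg) else NA_real_
      lead <- if (evaluable && !is.na(relapse_m) && !is.na(mol_month)) {
        compute_lead_time(mol_month, relapse_m)
      } else {
        NA_real_
      }

      remission_end <- if (!is.na(relapse_m)) relapse_m else Inf
      remission <- calls$month >= surg & calls$month < remission_end &
        calls$timepoint != "T4"
      ever_pos <- evaluable && any(calls$positivity[remission] == "positive")

      monitored_months <- calls$month[remission]
      in_denom <- evaluable && !is.na(relapse_m) &&
        any(relapse_m - monitored_months <= cfg$relapse_window_months &
          monitored_months < relapse_m)
      detected <- in_denom && !is.na(mol_month) && mol_month < relapse_m

      tibble::tibble(
        patient_id = pid,
        pcr = pcr,
        category = cls$category,
        category_reason = cls$reason,
        clinical_relapse_month = relapse_m,
        molecular_relapse_month = mol_month,
        lead_time_months = lead,
        ever_positive_remission = ever_pos,
        in_sensitivity_denominator = in_denom,
        detected = detected,
        positivity = list(calls)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mrd_monitor", class(out))
  attr(out, "config") <- cfg
  out
}

#' Summarize cohort-level monitoring results
#'
#' Aggregates per-patient monitoring into the study-level readout:
#' evaluability category counts, the long-format positivity matrix, the
#' detection-sensitivity fraction with its exact (Clopper-Pearson) 95%
#' interval, the mean molecular lead time over detected relapses (rounded
#' half-up to one decimal), ever-positive rates by pCR status, and — when
#' both margins are populated — the uncorrected Pearson chi-square on the
#' pCR-by-ever-positivity table.
#'
#' @param monitor An `mrd_monitor` from [monitor_cohort()].
#' @param cfg A [positivity_config()].
#' @return A list of class `mrd_summary`.
#' @export
summarize_cohort <- function(monitor, cfg = positivity_config()) {
  categories <- c(
    "evaluable", "insufficient_data", "low_baseline_signal", "germline_artifact"
  )
  category_counts <- tibble::tibble(
    category = categories,
    n = unname(vapply(categories, function(ct) sum(monitor$category == ct), numeric(1)))
  )

  positivity_matrix <- monitor |>
    dplyr::select("patient_id", "category", "positivity") |>
    tidyr::unnest("positivity")

  n_eligible <- sum(monitor$in_sensitivity_denominator)
  n_detected <- sum(monitor$detected)
  sensitivity_ci <- if (n_eligible > 0) {
    clopper_pearson(n_detected, n_eligible)
  } else {
    NULL
  }

  leads <- monitor$lead_time_months[monitor$detected]
  mean_lead <- if (length(leads)) round_half_up(mean(leads), 1) else NA_real_

  evaluable <- monitor[monitor$category == "evaluable", , drop = FALSE]
  tab <- NULL
  chi2 <- NULL
  if (nrow(evaluable)) {
    tab <- matrix(
      c(
        sum(evaluable$pcr & evaluable$ever_positive_remission),
        sum(!evaluable$pcr & evaluable$ever_positive_remission),
        sum(evaluable$pcr & !evaluable$ever_positive_remission),
        sum(!evaluable$pcr & !evaluable$ever_positive_remission)
      ),
      nrow = 2,
      dimnames = list(pcr = c("yes", "no"), ever_positive = c("yes", "no"))
    )
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chi2 <- pearson_chi2(tab)
    }
  }

  rate <- function(sub) {
    if (nrow(sub) == 0) NA_real_ else mean(sub$ever_positive_remission)
  }
  structure(
    list(
      n_patients = nrow(monitor),
      category_counts = category_counts,
      positivity_matrix = positivity_matrix,
      n_relapse_eligible = n_eligible,
      n_relapse_detected = n_detected,
      sensitivity = if (n_eligible > 0) n_detected / n_eligible else NA_real_,
      sensitivity_ci = sensitivity_ci,
      mean_lead_time_months = mean_lead,
      lead_times = leads,
      pcr_positive_rate = rate(evaluable[evaluable$pcr, , drop = FALSE]),
      non_pcr_positive_rate = rate(evaluable[!evaluable$pcr, , drop = FALSE]),
      contingency = tab,
      chi2 = chi2,
      config = cfg
    ),
    class = "mrd_summary"
  )
}

#' @export
print.mrd_summary <- function(x, ...) {
  cat(sprintf("ctDNA monitoring summary (%d patients)\n", x$n_patients))
  for (i in seq_len(nrow(x$category_counts))) {
    cat(sprintf(
      "  %-20s %d\n", x$category_counts$category[i], x$category_counts$n[i]
    ))
  }
  if (!is.na(x$sensitivity)) {
    cat(sprintf(
      "Relapse detection: %d/%d (%s), 95%% CI lower %s\n",
      x$n_relapse_detected, x$n_relapse_eligible, fmt_percent(x$sensitivity),
      fmt_percent(x$sensitivity_ci$lower)
    ))
  }
  if (!is.na(x$mean_lead_time_months)) {
    cat(sprintf("Mean lead time: %.1f months\n", x$mean_lead_time_months))
  }
  if (!is.null(x$chi2)) {
    cat(sprintf(
      "pCR association: ever-positive %s (pCR) vs %s (no pCR), chi-square p = %.3f\n",
      fmt_percent(x$pcr_positive_rate), fmt_percent(x$non_pcr_positive_rate),
      x$chi2$p_value
    ))
  }
  invisible(x)
}

#' @export
glance.mrd_summary <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n_patients,
    n_evaluable = x$category_counts$n[x$category_counts$category == "evaluable"],
    n_relapse_eligible = x$n_relapse_eligible,
    n_relapse_detected = x$n_relapse_detected,
    sensitivity = x$sensitivity,
    sensitivity_ci_lower = if (!is.null(x$sensitivity_ci)) x$sensitivity_ci$lower else NA_real_,
    mean_lead_time_months = x$mean_lead_time_months,
    pcr_positive_rate = x$pcr_positive_rate,
    non_pcr_positive_rate = x$non_pcr_positive_rate,
    chi2_p_value = if (!is.null(x$chi2)) x$chi2$p_value else NA_real_
  )
}
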