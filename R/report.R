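# Cohort report rendering: deterministic JSON + TSV + human-readable
# markdown, with percentages printed the way the clinical summary prints
# them (half-up; decimals kept only when exact).

#' Render a cohort monitoring report
#'
#' Builds a deterministic report structure (fixed key order) from a cohort
#' summary and optionally writes `report.json`, `summary.tsv` and
#' `report.md` to a directory. The JSON echoes the positivity
#' configuration, package version and seed so a run can be reproduced.
#'
#' @param summary An `mrd_summary` from [summarize_cohort()].
#' @param outdir Optional output directory (created if needed).
#' @param seed Seed to echo into the report.
#' @return The report list, invisibly when writing, otherwise visibly.
#' @export
render_report <- function(summary, outdir = NULL, seed = NULL) {
  stopifnot(inherits(summary, "mrd_summary"))
  cfg <- summary$config
  report <- list(
    software = list(
      package = "mrdtrace",
      version = as.character(packageVersion("mrdtrace")),
      seed = seed
    ),
    config = list(
      vaf_threshold = cfg$vaf_threshold,
      min_positive_variants = cfg$min_positive_variants,
      baseline_detectability_threshold = cfg$baseline_detectability_threshold,
      germline_vaf_flag = cfg$germline_vaf_flag,
      relapse_window_months = cfg$relapse_window_months
    ),
    cohort = list(
      n_patients = summary$n_patients,
      categories = setNames(
        as.list(summary$category_counts$n), summary$category_counts$category
      )
    ),
    detection = list(
      n_relapse_eligible = summary$n_relapse_eligible,
      n_relapse_detected = summary$n_relapse_detected,
      sensitivity = summary$sensitivity,
      sensitivity_percent = if (!is.na(summary$sensitivity)) {
        fmt_percent(summary$sensitivity)
      } else {
        NA_character_
      },
      sensitivity_ci_lower = if (!is.null(summary$sensitivity_ci)) {
        summary$sensitivity_ci$lower
      } else {
        NA_real_
      },
      mean_lead_time_months = summary$mean_lead_time_months,
      lead_times = summary$lead_times
    ),
    pcr_association = list(
      pcr_positive_rate = summary$pcr_positive_rate,
      pcr_positive_percent = fmt_percent(summary$pcr_positive_rate),
      non_pcr_positive_rate = summary$non_pcr_positive_rate,
      non_pcr_positive_percent = fmt_percent(summary$non_pcr_positive_rate),
      contingency = if (!is.null(summary$contingency)) {
        as.list(as.data.frame(summary$contingency))
      } else {
        NULL
      },
      chi2_statistic = if (!is.null(summary$chi2)) summary$chi2$statistic else NA_real_,
      chi2_p_value = if (!is.null(summary$chi2)) summary$chi2$p_value else NA_real_
    )
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report, file.path(outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
    write_tsv_hash(glance(summary), file.path(outdir, "summary.tsv"))
    writeLines(report_markdown(summary), file.path(outdir, "report.md"))
    return(invisible(report))
  }
  report
}

report_markdown <- function(summary) {
  lines <- c(
    "# ctDNA micro-panel monitoring report",
    "",
    sprintf("Patients: %d", summary$n_patients),
    "",
    "## Evaluability",
    sprintf(
      "- %s: %d", summary$category_counts$category, summary$category_counts$n
    ),
    "",
    "## Molecular relapse detection"
  )
  if (!is.na(summary$sensitivity)) {
    lines <- c(lines, sprintf(
      "- Detected %d of %d eligible relapses (%s); exact 95%% CI lower bound %s.",
      summary$n_relapse_detected, summary$n_relapse_eligible,
      fmt_percent(summary$sensitivity), fmt_percent(summary$sensitivity_ci$lower)
    ))
  } else {
    lines <- c(lines, "- No relapses eligible for sensitivity assessment (reported as NA).")
  }
  if (!is.na(summary$mean_lead_time_months)) {
    lines <- c(lines, sprintf(
      "- Mean molecular lead time: %.1f months.", summary$mean_lead_time_months
    ))
  }
  lines <- c(lines, "", "## Association with pathological complete response")
  if (!is.null(summary$chi2)) {
    lines <- c(lines, sprintf(
      "- Ever positive during remission: %s of pCR vs %s of non-pCR patients (chi-square p = %.3f).",
      fmt_percent(summary$pcr_positive_rate), fmt_percent(summary$non_pcr_positive_rate),
      summary$chi2$p_value
    ))
  } else {
    lines <- c(lines, "- Contingency table degenerate; no test performed.")
  }
  lines
}
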