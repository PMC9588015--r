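# Plotting: per-patient VAF trajectories and the cohort positivity grid.

#' Plot one patient's longitudinal VAF trajectory
#'
#' VAF of each panel variant against months since baseline on a log scale
#' (zero and failed-probe measurements are shown at the plot floor), with
#' the positivity threshold, surgery month and — when present — the
#' clinical relapse month marked.
#'
#' @param timeline An `mrd_timeline` from [assemble_timeline()].
#' @param patient A patient id present in the timeline.
#' @param cfg A [positivity_config()] (for the threshold line).
#' @param floor Display floor for zero/undefined VAFs (default 1e-6).
#' @return A ggplot object.
#' @export
plot_patient_timeline <- function(timeline, patient,
                                  cfg = positivity_config(), floor = 1e-6) {
  row <- timeline[timeline$patient_id == patient, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(sprintf("Patient %s not found in timeline.", patient),
      class = "mrdtrace_input_error"
    )
  }
  data <- row$data[[1]] |>
    dplyr::mutate(
      locus = paste0(.data$chrom, ":", .data$pos),
      vaf_display = pmax(dplyr::coalesce(.data$vaf, 0), floor)
    )
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$month, y = .data$vaf_display, colour = .data$locus)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$probe_pass)) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(
      yintercept = cfg$vaf_threshold, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_vline(
      xintercept = row$surgery_month, linetype = "dotted", colour = "grey40"
    ) +
    ggplot2::labs(
      title = sprintf("Patient %s: panel VAF trajectory", patient),
      x = "Months since baseline", y = "VAF (log scale)",
      colour = "Variant", shape = "Probe pass"
    ) +
    ggplot2::theme_minimal()
  if (!is.na(row$clinical_relapse_month)) {
    p <- p + ggplot2::geom_vline(
      xintercept = row$clinical_relapse_month, linetype = "longdash", colour = "red3"
    )
  }
  p
}

#' Positivity grid for a cohort summary
#'
#' Tile plot of per-patient, per-timepoint positivity calls (positive /
#' negative / indeterminate) across the monitoring schedule — the
#' cohort-level remission picture at a glance.
#'
#' @param object An `mrd_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrd_summary <- function(object, ...) {
  grid <- object$positivity_matrix
  ggplot2::ggplot(
    grid,
    ggplot2::aes(
      x = factor(.data$timepoint, levels = unique(.data$timepoint[order(.data$month)])),
      y = .data$patient_id, fill = .data$positivity
    )
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(
        positive = "darkorange2", negative = "seagreen4",
        indeterminate = "grey75"
      )
    ) +
    ggplot2::labs(
      x = "Timepoint", y = "Patient", fill = "ctDNA call",
      title = "Per-timepoint ctDNA positivity"
    ) +
    ggplot2::theme_minimal()
}
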