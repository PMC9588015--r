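# End-to-end pipeline: simulate -> design panels -> measure -> quantify ->
# monitor -> report, with optional artifact writing and a checksum
# manifest so identical seeds give identical outputs.

#' Run the full monitoring pipeline on a synthetic cohort
#'
#' Executes every stage in order: cohort simulation, variant filtering and
#' panel selection with pool layout, plasma measurements (template-level
#' by default; read-level runs the full FASTQ -> UMI -> consensus ->
#' allele-count path and is intended for desk-scale configurations), VAF
#' computation and probe QC, timeline assembly, patient monitoring, cohort
#' summary and report rendering. When `outdir` is given, every tabular
#' artifact is written as TSV/JSON together with an md5 checksum manifest;
#' a fixed config seed reproduces identical checksums.
#'
#' @param config A [cohort_config()].
#' @param filter_cfg,panel_cfg,positivity_cfg Stage configurations.
#' @param templates Unique templates per amplicon for template-level
#'   measurements.
#' @param background_error Post-consensus background substitution rate per
#'   template.
#' @param read_level Simulate and collapse individual UMI-tagged reads
#'   instead of template-level counts (slower; use small cohorts).
#' @param em An [error_model()] for read-level runs.
#' @param outdir Optional artifact directory.
#' @return A list with `cohort`, `panels`, `measurements`, `timeline`,
#'   `monitor`, `summary`, `report`, and `checksums` when `outdir` is set.
#' @export
run_pipeline <- function(config = cohort_config(),
                         filter_cfg = filter_config(),
                         panel_cfg = panel_config(),
                         positivity_cfg = positivity_config(),
                         templates = 20000,
                         background_error = 1e-5,
                         read_level = FALSE,
                         em = error_model(),
                         outdir = NULL) {
  cohort <- simulate_cohort(config)
  panels <- design_cohort_panels(cohort, filter_cfg, panel_cfg)

  measurements <- if (read_level) {
    measure_cohort_read_level(cohort, panels, em)
  } else {
    simulate_measurements(
      cohort, panels,
      templates = templates, background_error = background_error
    )
  }
  if (nrow(measurements) == 0) {
    abort("No measurements generated: check draw compliance and panels.",
      class = "mrdtrace_pipeline_error"
    )
  }
  measurements <- compute_vaf(measurements)

  clinical <- cohort[, c(
    "patient_id", "pcr", "surgery_month", "clinical_relapse_month",
    "last_followup_month"
  )]
  timeline <- assemble_timeline(measurements, clinical)
  monitor <- monitor_cohort(timeline, positivity_cfg)
  summary <- summarize_cohort(monitor, positivity_cfg)
  report <- render_report(summary, outdir = outdir, seed = config$seed)

  out <- list(
    cohort = cohort, panels = panels, measurements = measurements,
    timeline = timeline, monitor = monitor, summary = summary, report = report
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_panel_manifest(panels, file.path(outdir, "panel_manifest.tsv"))
    write_tsv_hash(
      dplyr::select(measurements, -dplyr::any_of("gene_symbol")),
      file.path(outdir, "measurements.tsv")
    )
    write_tsv_hash(clinical, file.path(outdir, "clinical.tsv"))
    write_tsv_hash(
      dplyr::select(monitor, -"positivity"),
      file.path(outdir, "monitoring.tsv")
    )
    write_tsv_hash(summary$positivity_matrix, file.path(outdir, "positivity_matrix.tsv"))
    writeLines(
      yaml::as.yaml(unclass(config)), file.path(outdir, "cohort_config.yaml")
    )
    files <- sort(setdiff(list.files(outdir, full.names = TRUE), file.path(outdir, "checksums.tsv")))
    checksums <- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
    write_tsv_hash(checksums, file.path(outdir, "checksums.tsv"))
    out$checksums <- checksums
  }
  out
}

# Read-level measurement path: per patient and draw, simulate UMI-tagged
# reads for the panel at the draw's true fraction, run the consensus
# stack, and count alleles at each locus.
measure_cohort_read_level <- function(cohort, panels, em = error_model()) {
  cfc <- consensus_filter_config()
  purrr::pmap(
    list(cohort$patient_id, cohort$draws, cohort$germline_artifact),
    function(pid, draws, germline) {
      panel <- panels[panels$patient_id == pid, , drop = FALSE]
      if (nrow(panel) == 0 || nrow(draws) == 0) {
        return(NULL)
      }
      panel <- build_amplicon_sequences(panel)
      purrr::pmap(
        list(draws$timepoint, draws$month, draws$true_fraction),
        function(tp, month, frac) {
          af <- rep(min(frac, 1), nrow(panel))
          if (germline) af[1] <- 0.998
          counts <- collapse_and_count(panel, af, em, cfc)
          dplyr::mutate(counts, patient_id = pid, timepoint = tp, month = month)
        }
      ) |>
        dplyr::bind_rows()
    }
  ) |>
    dplyr::bind_rows()
}

#' Collapse simulated reads for one sample and count alleles
#'
#' Desk-scale helper running the complete read path for one panel and
#' allele-fraction vector: read simulation, UMI extraction, amplicon
#' assignment, family grouping, consensus calling and filtering, and
#' allele counting. The simulated truth is attached as attribute `truth`.
#'
#' @param panel Panel with amplicon sequences ([build_amplicon_sequences()]).
#' @param signal_fraction Allele fraction(s) at the panel loci.
#' @param em An [error_model()].
#' @param cfg A [consensus_filter_config()].
#' @return Locus read counts as from [count_alleles()].
#' @export
collapse_and_count <- function(panel, signal_fraction, em = error_model(),
                               cfg = consensus_filter_config()) {
  sim <- simulate_amplicon_reads(panel, signal_fraction, em)
  tagged <- extract_umi(sim$reads, em$umi_length)
  tagged <- assign_amplicon(tagged, panel[, c("amplicon_id", "anchor")])
  raw_cov <- table(tagged$amplicon_id[!is.na(tagged$amplicon_id)])
  fams <- group_families(tagged, cfg)
  cons <- call_consensus(fams, cfg)
  cons <- filter_consensus(cons, cfg)
  counts <- count_alleles(cons, panel, raw_coverage = raw_cov)
  attr(counts, "truth") <- sim$truth
  counts
}
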