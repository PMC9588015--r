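# Allele counting at panel loci from passing consensus reads, VAF
# computation, the low-performing-probe rule (< 1,000x observed raw
# coverage), and longitudinal timeline assembly.

#' Count alleles at panel loci from passing consensus reads
#'
#' Each passing consensus read covering a locus contributes exactly once:
#' to `ref_count`, `alt_count`, `other_count` (a third base) or
#' `no_call_count` (N at the locus). Raw coverage — reads assigned to the
#' amplicon before consensus, the "observed coverage" of the probe rule —
#' is taken from `raw_coverage` (a named vector per amplicon) when given.
#'
#' @param consensus Filtered consensus table ([filter_consensus()]).
#' @param panel Panel with `amplicon_id`, `variant_offset`, `ref_allele`,
#'   `alt_allele` (plus locus columns carried through).
#' @param raw_coverage Optional named vector: raw assigned reads per
#'   amplicon; defaults to total consensus-family member counts.
#' @return A tibble with one row per panel locus: counts, consensus depth
#'   and raw coverage. Count conservation holds by construction:
#'   ref + alt + other + no_call = consensus_depth.
#' @export
count_alleles <- function(consensus, panel, raw_coverage = NULL) {
  check_columns(
    panel, c("amplicon_id", "variant_offset", "ref_allele", "alt_allele"),
    "Panel"
  )
  passing <- consensus[consensus$filter_status == "pass", , drop = FALSE]
  purrr::pmap(
    list(
      panel$amplicon_id, panel$variant_offset,
      panel$ref_allele, panel$alt_allele
    ),
    function(amp, off, ref, alt) {
      covering <- passing[passing$amplicon_id == amp, , drop = FALSE]
      base <- substr(covering$consensus, off + 1, off + 1)
      raw <- if (!is.null(raw_coverage)) {
        as.integer(raw_coverage[[amp]] %||% 0L)
      } else {
        amp_fams <- consensus[consensus$amplicon_id == amp, , drop = FALSE]
        as.integer(sum(amp_fams$family_size))
      }
      tibble::tibble(
        amplicon_id = amp,
        ref_count = sum(base == ref),
        alt_count = sum(base == alt),
        no_call_count = sum(base == "N"),
        other_count = length(base) - sum(base %in% c(ref, alt, "N")),
        consensus_depth = length(base),
        raw_coverage = raw
      )
    }
  ) |>
    dplyr::bind_rows() |>
    (\(counts) dplyr::bind_cols(
      panel[, intersect(
        c("patient_id", "chrom", "pos", "ref_allele", "alt_allele", "gene_symbol"),
        names(panel)
      )],
      counts
    ))()
}

#' Compute variant allele fractions
#'
#' VAF = alt / (ref + alt + other); no-calls are excluded from the
#' denominator. A locus with zero evaluable depth has an undefined VAF
#' (`NA`). The probe-level QC flag ([probe_qc()]) is attached.
#'
#' @param readcounts Locus read counts from [count_alleles()] (or the
#'   template-level simulator).
#' @param min_raw_coverage Probe-QC floor on raw coverage (default 1000).
#' @return `readcounts` with `vaf` and `probe_pass` columns.
#' @export
compute_vaf <- function(readcounts, min_raw_coverage = 1000) {
  check_columns(
    readcounts,
    c("ref_count", "alt_count", "other_count", "raw_coverage"),
    "Readcount table"
  )
  denom <- readcounts$ref_count + readcounts$alt_count + readcounts$other_count
  dplyr::mutate(
    readcounts,
    vaf = ifelse(denom > 0, .data$alt_count / denom, NA_real_),
    probe_pass = probe_qc(.data$raw_coverage, min_raw_coverage)
  )
}

#' Low-performing-probe rule
#'
#' A probe (panel amplicon) underperforms in a sample when its observed
#' raw coverage is below 1,000x; such measurements are retained but
#' excluded from positivity calling.
#'
#' @param raw_coverage Raw reads assigned to the amplicon.
#' @param min_raw_coverage Threshold (default 1000; pass is inclusive).
#' @return Logical vector: `TRUE` when the probe passes.
#' @export
probe_qc <- function(raw_coverage, min_raw_coverage = 1000) {
  raw_coverage >= min_raw_coverage
}

#' Assemble per-patient longitudinal timelines
#'
#' Joins VAF measurements to clinical metadata and nests them into one row
#' per patient with draws sorted by month. Duplicate
#' (patient, timepoint, locus) rows and measurements for patients absent
#' from the clinical table are input errors.
#'
#' @param measurements Long tibble of VAF measurements (needs
#'   `patient_id`, `timepoint`, `month`, `pos`, `vaf`, `probe_pass`).
#' @param clinical Clinical table: `patient_id`, `pcr`, `surgery_month`,
#'   `clinical_relapse_month` (`NA` = none), `last_followup_month`.
#' @return A tibble of class `mrd_timeline`: clinical columns plus a
#'   `data` list-column of per-draw measurements.
#' @export
assemble_timeline <- function(measurements, clinical) {
  check_columns(
    measurements,
    c("patient_id", "timepoint", "month", "pos", "vaf", "probe_pass"),
    "Measurement table"
  )
  check_columns(
    clinical,
    c("patient_id", "pcr", "surgery_month", "clinical_relapse_month", "last_followup_month"),
    "Clinical table"
  )
  unknown <- setdiff(measurements$patient_id, clinical$patient_id)
  if (length(unknown)) {
    abort(
      sprintf(
        "Measurements reference patient(s) absent from the clinical table: %s.",
        paste(unknown, collapse = ", ")
      ),
      class = "mrdtrace_input_error"
    )
  }
  dup <- measurements |>
    dplyr::count(.data$patient_id, .data$timepoint, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(
      sprintf(
        "Duplicate measurement rows (e.g. patient %s, timepoint %s).",
        dup$patient_id[1], dup$timepoint[1]
      ),
      class = "mrdtrace_input_error"
    )
  }

  nested <- measurements |>
    dplyr::arrange(.data$patient_id, .data$month, .data$pos) |>
    dplyr::group_by(.data$patient_id) |>
    tidyr::nest(.key = "data") |>
    dplyr::ungroup()

  out <- clinical |>
    dplyr::inner_join(nested, by = "patient_id") |>
    dplyr::arrange(.data$patient_id)
  class(out) <- c("mrd_timeline", class(out))
  out
}
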