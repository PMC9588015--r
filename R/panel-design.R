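# Tumor-informed micro-panel design: somatic-variant filtering, the
# TP53-anchored selection heuristic, primer-pool layout, and germline BRCA
# flagging from a supplied classification table.

#' Somatic variant filter configuration
#'
#' The five exclusion criteria applied to tumor/normal somatic calls before
#' panel selection: previously known (database) variants, variants with high
#' population allele frequency, variants supported by a high fraction of
#' MQ0 (ambiguously mapped) reads, low-depth variants, and low-confidence
#' calls. The numeric thresholds are conventional somatic-filtering defaults
#' and fully configurable; the criteria themselves are fixed.
#'
#' @param max_population_af Maximum population allele frequency (default
#'   0.001).
#' @param max_mq0_fraction Maximum fraction of MQ0 reads (default 0.10).
#' @param min_depth Minimum sequencing depth (default 20).
#' @param exclude_known Drop previously known variants? Default `TRUE`.
#' @param exclude_low_confidence Drop low-confidence calls? Default `TRUE`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_population_af = 0.001,
                          max_mq0_fraction = 0.10,
                          min_depth = 20,
                          exclude_known = TRUE,
                          exclude_low_confidence = TRUE) {
  check_probability(max_population_af, "max_population_af")
  check_probability(max_mq0_fraction, "max_mq0_fraction")
  if (min_depth < 0) abort("min_depth must be non-negative.", class = "mrdtrace_config_error")
  structure(
    list(
      max_population_af = max_population_af,
      max_mq0_fraction = max_mq0_fraction,
      min_depth = min_depth,
      exclude_known = isTRUE(exclude_known),
      exclude_low_confidence = isTRUE(exclude_low_confidence)
    ),
    class = "filter_config"
  )
}

#' Filter somatic variants for panel eligibility
#'
#' Applies the exclusion criteria of [filter_config()], preserving input
#' order. Records missing any required covariate are rejected with a
#' message (never silently passed). Filtering is idempotent.
#'
#' @param variants Tibble of somatic variants (one row per variant) with
#'   columns `population_af`, `mq0_fraction`, `depth`, `known_variant`,
#'   `confidence`.
#' @param cfg A [filter_config()].
#' @return The subset of `variants` passing every enabled criterion.
#' @export
filter_variants <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0) {
    return(variants)
  }
  covars <- c("population_af", "mq0_fraction", "depth", "known_variant", "confidence")
  check_columns(variants, covars, "Variant table")
  complete <- complete.cases(variants[, covars])
  if (any(!complete)) {
    inform(sprintf(
      "%d variant record(s) rejected: missing filter covariates.", sum(!complete)
    ))
  }
  keep <- complete &
    variants$population_af <= cfg$max_population_af &
    variants$mq0_fraction <= cfg$max_mq0_fraction &
    variants$depth >= cfg$min_depth &
    (!cfg$exclude_known | !variants$known_variant) &
    (!cfg$exclude_low_confidence | variants$confidence == "high")
  variants[keep, , drop = FALSE]
}

#' Micro-panel selection configuration
#'
#' Panels hold 1-6 variants; the design aims for 4 amplicons per patient
#' (every non-silent TP53 variant plus up to three top-VAF supplements) and
#' primer pools are capped at about 100 amplicon primer pairs.
#'
#' @param target_size Desired panel size (default 4).
#' @param max_size Hard maximum panel size (default 6).
#' @param min_size Minimum panel size (default 1).
#' @param n_extra_top_vaf Maximum supplements added on top of the TP53
#'   anchors (default 3); when a patient has no non-silent TP53 variant the
#'   panel is simply filled to `target_size` by descending VAF.
#' @param max_primer_pairs_per_pool Primer-pair capacity of one pool
#'   (default 100).
#' @param amplicon_flank Bases of amplicon context on each side of the
#'   variant locus (default 75; amplicons are stored 0-based half-open).
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(target_size = 4,
                         max_size = 6,
                         min_size = 1,
                         n_extra_top_vaf = 3,
                         max_primer_pairs_per_pool = 100,
                         amplicon_flank = 75) {
  if (!(min_size <= target_size && target_size <= max_size && max_size <= 6)) {
    abort("Need min_size <= target_size <= max_size <= 6.",
      class = "mrdtrace_config_error"
    )
  }
  structure(
    list(
      target_size = as.integer(target_size),
      max_size = as.integer(max_size),
      min_size = as.integer(min_size),
      n_extra_top_vaf = as.integer(n_extra_top_vaf),
      max_primer_pairs_per_pool = as.integer(max_primer_pairs_per_pool),
      amplicon_flank = as.integer(amplicon_flank)
    ),
    class = "panel_config"
  )
}

#' Select a patient's micro-panel targets
#'
#' Implements the tumor-informed selection heuristic: every non-silent TP53
#' variant is anchored into the panel (if the anchors alone exceed
#' `max_size`, the top-VAF `max_size` of them are kept), then remaining
#' variants — including silent TP53 variants, which rank as ordinary
#' candidates — are added by descending tissue VAF until the panel reaches
#' `min(target_size, available)`, never exceeding `max_size` and never
#' adding more than `n_extra_top_vaf` supplements when TP53 anchors exist.
#' Ties are broken by higher depth, then ascending (chrom, pos), so the
#' selection is a deterministic, order-independent function of the table.
#'
#' @param variants Filtered somatic variants for one patient.
#' @param cfg A [panel_config()].
#' @return A tibble of selected variants with amplicon coordinates
#'   (`amplicon_start`/`amplicon_end`, 0-based half-open), `amplicon_id`
#'   and `primer_pair_id`.
#' @export
select_panel <- function(variants, cfg = panel_config()) {
  check_columns(
    variants,
    c(
      "patient_id", "chrom", "pos", "gene_symbol", "consequence_class",
      "tissue_vaf", "depth"
    ),
    "Variant table"
  )
  if (nrow(variants) == 0) {
    abort("No variants available for panel design.",
      class = "mrdtrace_panel_error"
    )
  }
  pid <- unique(variants$patient_id)
  if (length(pid) != 1) {
    abort("select_panel() expects variants from a single patient.",
      class = "mrdtrace_input_error"
    )
  }

  ord <- order(
    -variants$tissue_vaf, -variants$depth,
    variants$chrom, variants$pos
  )
  variants <- variants[ord, , drop = FALSE]
  is_anchor <- variants$gene_symbol == "TP53" &
    variants$consequence_class != "silent"

  anchors <- variants[is_anchor, , drop = FALSE]
  if (nrow(anchors) > cfg$max_size) anchors <- anchors[seq_len(cfg$max_size), , drop = FALSE]

  candidates <- variants[!is_anchor, , drop = FALSE]
  n_extra_cap <- if (nrow(anchors) > 0) cfg$n_extra_top_vaf else cfg$max_size
  room <- min(
    cfg$target_size - nrow(anchors),
    cfg$max_size - nrow(anchors),
    n_extra_cap
  )
  n_extra <- max(0, min(room, nrow(candidates)))
  panel <- dplyr::bind_rows(anchors, candidates[seq_len(n_extra), , drop = FALSE])

  flank <- cfg$amplicon_flank
  panel |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(
      amplicon_start = .data$pos - 1L - flank,
      amplicon_end = .data$pos + flank,
      amplicon_id = sprintf("%s_amp%02d", pid, dplyr::row_number()),
      primer_pair_id = sprintf("%s_pp%02d", pid, dplyr::row_number())
    )
}

#' Design panels for a whole cohort
#'
#' Convenience wrapper: filters each patient's variant profile and selects
#' the micro-panel, then lays out primer pools across patients.
#'
#' @param cohort A cohort from [simulate_cohort()], or a tibble with a
#'   `variants` list-column.
#' @param filter_cfg A [filter_config()].
#' @param panel_cfg A [panel_config()].
#' @return A tibble of panel targets for all patients with `pool_id`
#'   assigned.
#' @export
design_cohort_panels <- function(cohort,
                                 filter_cfg = filter_config(),
                                 panel_cfg = panel_config()) {
  panels <- purrr::map(cohort$variants, function(v) {
    kept <- filter_variants(v, filter_cfg)
    if (nrow(kept) == 0) {
      warn(sprintf(
        "Patient %s: no variants survive filtering; no panel designed.",
        unique(v$patient_id)
      ))
      return(NULL)
    }
    select_panel(kept, panel_cfg)
  }) |>
    dplyr::bind_rows()
  build_pools(panels, panel_cfg)
}

#' Assign panels to primer pools
#'
#' Greedy first-fit bin packing of panels (one primer pair per target) into
#' pools capped at `max_primer_pairs_per_pool`, keeping each patient's
#' primer pairs together in a single pool.
#'
#' @param panels Panel targets for one or more patients (rows grouped by
#'   `patient_id`).
#' @param cfg A [panel_config()].
#' @return `panels` with a `pool_id` column.
#' @export
build_pools <- function(panels, cfg = panel_config()) {
  if (nrow(panels) == 0) {
    return(dplyr::mutate(panels, pool_id = character(0)))
  }
  sizes <- table(panels$patient_id)
  if (any(sizes > cfg$max_primer_pairs_per_pool)) {
    abort("A single panel exceeds the primer-pair pool capacity.",
      class = "mrdtrace_layout_error"
    )
  }
  load <- integer(0)
  assignment <- character(0)
  for (pid in unique(panels$patient_id)) {
    need <- sizes[[pid]]
    slot <- which(load + need <= cfg$max_primer_pairs_per_pool)[1]
    if (is.na(slot)) {
      load <- c(load, need)
      slot <- length(load)
    } else {
      load[slot] <- load[slot] + need
    }
    assignment[pid] <- sprintf("pool%02d", slot)
  }
  dplyr::mutate(panels, pool_id = unname(assignment[.data$patient_id]))
}

#' Flag germline BRCA1/BRCA2 status from a classification table
#'
#' Determines per-patient germline BRCA status from called germline
#' variants and a user-supplied pathogenicity classification table (the
#' curated lookup that would otherwise come from clinical variant
#' databases). A patient is positive if at least one BRCA1/BRCA2 variant is
#' classified Pathogenic or Likely pathogenic without conflict; a variant
#' carrying both pathogenic and non-pathogenic classifications makes the
#' patient indeterminate unless another cleanly pathogenic variant exists.
#'
#' @param germline_variants Tibble with `patient_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `gene_symbol`.
#' @param classification_table Tibble with `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `classification` (values such as "Pathogenic", "Likely
#'   pathogenic", "Benign", "VUS").
#' @return Tibble with `patient_id` and `brca_status` in
#'   `positive_BRCA1`, `positive_BRCA2`, `negative`, `indeterminate`.
#' @export
flag_brca_germline <- function(germline_variants, classification_table) {
  check_columns(
    germline_variants,
    c("patient_id", "chrom", "pos", "ref_allele", "alt_allele", "gene_symbol"),
    "Germline variant table"
  )
  check_columns(
    classification_table,
    c("chrom", "pos", "ref_allele", "alt_allele", "classification"),
    "Classification table"
  )
  bad <- !complete.cases(
    classification_table[, c("chrom", "pos", "ref_allele", "alt_allele", "classification")]
  )
  if (any(bad)) {
    inform(sprintf("%d malformed classification row(s) rejected.", sum(bad)))
    classification_table <- classification_table[!bad, , drop = FALSE]
  }

  pathogenic <- c("Pathogenic", "Likely pathogenic")
  per_variant <- classification_table |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(
      any_path = any(.data$classification %in% pathogenic),
      any_benign = any(!.data$classification %in% pathogenic),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      variant_call = dplyr::case_when(
        .data$any_path & !.data$any_benign ~ "pathogenic",
        .data$any_path & .data$any_benign ~ "conflict",
        TRUE ~ "not_pathogenic"
      )
    )

  germline_variants |>
    dplyr::filter(.data$gene_symbol %in% c("BRCA1", "BRCA2")) |>
    dplyr::left_join(
      per_variant,
      by = c("chrom", "pos", "ref_allele", "alt_allele")
    ) |>
    dplyr::mutate(variant_call = tidyr::replace_na(.data$variant_call, "not_pathogenic")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      brca_status = dplyr::case_when(
        any(.data$variant_call == "pathogenic" & .data$gene_symbol == "BRCA1") ~ "positive_BRCA1",
        any(.data$variant_call == "pathogenic" & .data$gene_symbol == "BRCA2") ~ "positive_BRCA2",
        any(.data$variant_call == "conflict") ~ "indeterminate",
        TRUE ~ "negative"
      ),
      .groups = "drop"
    ) |>
    (\(brca) dplyr::bind_rows(
      brca,
      tibble::tibble(
        patient_id = setdiff(unique(germline_variants$patient_id), brca$patient_id),
        brca_status = "negative"
      )
    ))() |>
    dplyr::arrange(.data$patient_id)
}
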