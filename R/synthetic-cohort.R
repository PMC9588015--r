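# Synthetic cohort generator. Emulates the statistical structure of a
# neoadjuvant TNBC ctDNA-monitoring study: per-tumor somatic variant burden
# (median 77.5, range clipped to [1, 1970]), 86% prevalence of non-silent
# TP53 mutations, tissue VAFs centred on 32.9% and baseline plasma VAFs on
# 0.33%, a T0 / C1D3 / surgery / q6-month draw schedule with imperfect
# compliance, and relapse trajectories whose molecular onset precedes
# clinical relapse by 2-7 months. Every record carries full ground truth so
# downstream detection and classification can be scored exactly.

PANEL_GENES <- c(
  "PIK3CA", "PTEN", "RB1", "NF1", "ARID1A", "KMT2C", "NOTCH1", "MYC",
  "GATA3", "CDH1", "BRCA1", "BRCA2", "AKT1", "ERBB2", "ESR1", "FOXA1",
  "MAP3K1", "SMAD4", "FAT1", "USH2A"
)

CONSEQUENCE_CLASSES <- c(
  "silent", "missense", "nonsense", "frameshift", "splice",
  "inframe_indel", "other_nonsilent"
)

#' Configuration for the synthetic monitoring cohort
#'
#' Bundles every tunable of the cohort generator with defaults matching the
#' motivating study: 50 patients, a 14% clinical relapse rate and 34% pCR
#' rate, a log-normal variant-burden law with median 77.5 clipped to
#' \[1, 1970\], 86% probability of at least one non-silent TP53 variant,
#' mean tissue VAF 0.329, mean baseline plasma VAF 0.0033, draws at baseline
#' (T0, month 0), Cycle 1 Day 3 (T1), surgery (T2, month 5) and every 6
#' months thereafter, and molecular-relapse lead times uniform on 2-7
#' months.
#'
#' @param n_patients Cohort size.
#' @param relapse_rate Probability a patient clinically relapses during
#'   follow-up.
#' @param pcr_rate Probability of pathological complete response.
#' @param variant_count_meanlog,variant_count_sdlog Log-scale location and
#'   spread of the per-tumor somatic variant count.
#' @param variant_count_clip Two-element hard clip bounds on the count.
#' @param tp53_prob Probability a tumor carries at least one non-silent TP53
#'   variant.
#' @param tissue_vaf_mean Mean tumor-tissue VAF (fraction).
#' @param tissue_vaf_conc Beta concentration (a + b) for tissue VAF draws.
#' @param blood_vaf_mean_baseline Mean baseline plasma tumor fraction.
#' @param blood_vaf_sdlog Log-scale spread of the baseline plasma fraction.
#' @param c1d3_multiplier Multiplier applied to the baseline fraction at the
#'   Cycle 1 Day 3 draw (an early-treatment release of tumor DNA; a free
#'   parameter, not an inferred quantity).
#' @param lead_time_range Uniform support (months) of the molecular lead
#'   time before clinical relapse.
#' @param relapse_onset_fraction Plasma tumor fraction at molecular onset.
#' @param relapse_growth_per_month Multiplicative growth of the relapse
#'   signal per month after onset (capped at `relapse_max_fraction`).
#' @param relapse_max_fraction Cap on the relapse plasma fraction.
#' @param surgery_month Months from baseline to surgical resection.
#' @param followup_months Total follow-up from baseline.
#' @param draw_interval_months Spacing of post-surgical surveillance draws.
#' @param draw_compliance Probability each scheduled draw is actually
#'   collected.
#' @param germline_artifact_prob Probability a patient's panel contains a
#'   germline variant that reads out near 100% VAF in plasma.
#' @param low_baseline_threshold Baseline plasma fraction below which a
#'   patient's markers are considered undetectable at baseline (0.05%).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 50,
                          relapse_rate = 0.14,
                          pcr_rate = 0.34,
                          variant_count_meanlog = log(77.5),
                          variant_count_sdlog = 1.4,
                          variant_count_clip = c(1, 1970),
                          tp53_prob = 0.86,
                          tissue_vaf_mean = 0.329,
                          tissue_vaf_conc = 10,
                          blood_vaf_mean_baseline = 0.0033,
                          blood_vaf_sdlog = 1.0,
                          c1d3_multiplier = 1.5,
                          lead_time_range = c(2, 7),
                          relapse_onset_fraction = 0.002,
                          relapse_growth_per_month = 1.6,
                          relapse_max_fraction = 0.05,
                          surgery_month = 5,
                          followup_months = 48,
                          draw_interval_months = 6,
                          draw_compliance = 0.8,
                          germline_artifact_prob = 0.04,
                          low_baseline_threshold = 5e-4,
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients", min = 1),
    relapse_rate = check_probability(relapse_rate, "relapse_rate"),
    pcr_rate = check_probability(pcr_rate, "pcr_rate"),
    variant_count_meanlog = variant_count_meanlog,
    variant_count_sdlog = variant_count_sdlog,
    variant_count_clip = variant_count_clip,
    tp53_prob = check_probability(tp53_prob, "tp53_prob"),
    tissue_vaf_mean = check_probability(tissue_vaf_mean, "tissue_vaf_mean"),
    tissue_vaf_conc = tissue_vaf_conc,
    blood_vaf_mean_baseline = check_probability(
      blood_vaf_mean_baseline, "blood_vaf_mean_baseline"
    ),
    blood_vaf_sdlog = blood_vaf_sdlog,
    c1d3_multiplier = c1d3_multiplier,
    lead_time_range = lead_time_range,
    relapse_onset_fraction = relapse_onset_fraction,
    relapse_growth_per_month = relapse_growth_per_month,
    relapse_max_fraction = relapse_max_fraction,
    surgery_month = surgery_month,
    followup_months = followup_months,
    draw_interval_months = draw_interval_months,
    draw_compliance = check_probability(draw_compliance, "draw_compliance"),
    germline_artifact_prob = check_probability(
      germline_artifact_prob, "germline_artifact_prob"
    ),
    low_baseline_threshold = low_baseline_threshold,
    seed = as.integer(seed)
  )
  if (cfg$variant_count_clip[1] > cfg$variant_count_clip[2]) {
    abort("variant_count_clip bounds must be ordered.", class = "mrdtrace_config_error")
  }
  if (cfg$followup_months <= 0 || cfg$surgery_month <= 0 ||
    cfg$surgery_month >= cfg$followup_months) {
    abort("Need 0 < surgery_month < followup_months.", class = "mrdtrace_config_error")
  }
  if (cfg$lead_time_range[1] > cfg$lead_time_range[2] || cfg$lead_time_range[1] < 0) {
    abort("lead_time_range must be ordered and non-negative.",
      class = "mrdtrace_config_error"
    )
  }
  if (cfg$draw_interval_months <= 0) {
    abort("draw_interval_months must be positive.", class = "mrdtrace_config_error")
  }
  structure(cfg, class = "cohort_config")
}

# Nominal draw schedule implied by a config: T0, C1D3 (T1), surgery (T2),
# then q-interval surveillance draws (T3.k) until end of follow-up.
draw_schedule <- function(config) {
  t3_months <- seq(
    config$surgery_month + config$draw_interval_months,
    config$followup_months,
    by = config$draw_interval_months
  )
  tibble::tibble(
    timepoint = c("T0", "T1", "T2", sprintf("T3.%d", seq_along(t3_months))),
    month = c(0, 0.1, config$surgery_month, t3_months)
  )
}

#' Simulate one tumor's somatic variant profile
#'
#' Draws a per-tumor somatic variant table: the variant count is log-normal
#' (median at `exp(variant_count_meanlog)`) hard-clipped to the configured
#' bounds, tissue VAFs follow a Beta law centred on `tissue_vaf_mean`, and a
#' non-silent TP53 variant is present with probability `tp53_prob`. Filter
#' covariates (population allele frequency, MQ0 fraction, depth, known-site
#' and confidence flags) are drawn so a realistic minority of variants fails
#' each criterion.
#'
#' @param config A [cohort_config()].
#' @param patient_id Identifier stamped on every row.
#' @return A tibble of somatic variants (one row per variant).
#' @export
simulate_variant_profile <- function(config, patient_id = "P001") {
  n_raw <- round(rlnorm(1, config$variant_count_meanlog, config$variant_count_sdlog))
  n <- as.integer(min(max(n_raw, config$variant_count_clip[1]), config$variant_count_clip[2]))

  has_tp53 <- runif(1) < config$tp53_prob
  n_tp53 <- if (has_tp53) sample(1:2, 1, prob = c(0.8, 0.2)) else 0L
  n_tp53 <- min(n_tp53, n)

  gene <- c(
    rep("TP53", n_tp53),
    sample(PANEL_GENES, n - n_tp53, replace = TRUE)
  )
  consequence <- character(n)
  # TP53 rows forced non-silent (that is what tp53_prob means here); others
  # get a realistic consequence mix, about a quarter silent.
  nonsilent <- setdiff(CONSEQUENCE_CLASSES, "silent")
  consequence[seq_len(n_tp53)] <- sample(
    c("missense", "nonsense", "frameshift", "splice"), n_tp53,
    replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05)
  )
  if (n > n_tp53) {
    consequence[(n_tp53 + 1):n] <- sample(
      CONSEQUENCE_CLASSES, n - n_tp53,
      replace = TRUE,
      prob = c(0.25, 0.45, 0.08, 0.08, 0.05, 0.04, 0.05)
    )
  }

  mean_vaf <- config$tissue_vaf_mean
  shape1 <- mean_vaf * config$tissue_vaf_conc
  shape2 <- (1 - mean_vaf) * config$tissue_vaf_conc

  tibble::tibble(
    patient_id = patient_id,
    chrom = ifelse(gene == "TP53", "chr17",
      paste0("chr", sample(1:22, n, replace = TRUE))
    ),
    pos = sample(1e6:2e8, n, replace = TRUE),
    ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_allele = NA_character_,
    gene_symbol = gene,
    consequence_class = consequence,
    tissue_vaf = rbeta(n, shape1, shape2),
    depth = rpois(n, 80),
    population_af = ifelse(runif(n) < 0.05, runif(n, 0.001, 0.2), 0),
    mq0_fraction = rbeta(n, 0.5, 12),
    known_variant = runif(n) < 0.03,
    confidence = ifelse(runif(n) < 0.95, "high", "low")
  ) |>
    dplyr::mutate(
      alt_allele = purrr::map2_chr(
        .data$ref_allele, seq_len(n),
        function(ref, i) sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      )
    )
}

#' Simulate a plasma tumor-fraction trajectory
#'
#' Produces the true circulating tumor fraction at each scheduled draw. The
#' baseline (T0) value is the patient's plasma level; Cycle 1 Day 3 scales
#' it by `c1d3_multiplier`; from surgery onward the fraction is exactly zero
#' unless the patient relapses, in which case the signal reappears at
#' `clinical_relapse_month - lead_time` at `relapse_onset_fraction` and
#' grows geometrically until clinical relapse.
#'
#' @param config A [cohort_config()].
#' @param schedule Tibble with `timepoint` and `month` columns (a nominal
#'   draw schedule; see the cohort generator).
#' @param baseline_fraction True plasma tumor fraction at T0.
#' @param clinical_relapse_month Month of clinical relapse, or `NA`.
#' @param lead_time Months by which molecular onset precedes clinical
#'   relapse (ignored when no relapse).
#' @return The schedule tibble with a `true_fraction` column.
#' @export
simulate_trajectory <- function(config, schedule, baseline_fraction,
                                clinical_relapse_month = NA_real_,
                                lead_time = NA_real_) {
  onset <- NA_real_
  if (!is.na(clinical_relapse_month)) {
    onset <- clinical_relapse_month - lead_time
    if (onset < config$surgery_month) {
      # A lead time reaching back past surgery is clamped to the surgery
      # draw (persistent residual disease rather than re-emergence).
      inform(sprintf(
        "Lead time %.1f exceeds surgery-to-relapse interval; onset clamped to surgery month %.1f.",
        lead_time, config$surgery_month
      ))
      onset <- config$surgery_month
    }
  }
  frac <- purrr::map_dbl(schedule$month, function(m) {
    if (m < config$surgery_month) {
      mult <- if (m > 0) config$c1d3_multiplier else 1
      return(min(baseline_fraction * mult, 1))
    }
    if (is.na(onset) || m < onset || m > clinical_relapse_month) {
      return(0)
    }
    min(
      config$relapse_onset_fraction * config$relapse_growth_per_month^(m - onset),
      config$relapse_max_fraction
    )
  })
  dplyr::mutate(schedule, true_fraction = frac)
}

#' Simulate a monitoring cohort with full ground truth
#'
#' Generates `n_patients` truth records: outcome assignments (pCR and
#' relapse are independent Bernoulli draws at the configured rates), a
#' somatic variant profile per tumor, a plasma tumor-fraction trajectory on
#' the nominal draw schedule, the realized (compliance-thinned) draw list,
#' and the expected evaluability label. Molecular onset for relapse patients
#' is placed on a scheduled surveillance draw and clinical relapse follows
#' `lead_time` months later, so that with compliant draws the molecular
#' relapse is recoverable exactly.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `mrd_cohort` with one row per patient and
#'   list-columns `variants` (somatic profile), `trajectory`
#'   (schedule + true fractions) and `draws` (realized draws with labels);
#'   scalar columns carry outcomes and truth labels.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  schedule <- draw_schedule(config)
  t3 <- schedule$month[schedule$month > config$surgery_month]

  records <- purrr::map(seq_len(config$n_patients), function(i) {
    pid <- sprintf("SYN%03d", i)
    pcr <- runif(1) < config$pcr_rate
    relapse <- runif(1) < config$relapse_rate

    clinical_relapse_month <- NA_real_
    lead_time <- NA_real_
    onset <- NA_real_
    if (relapse) {
      lead_time <- runif(1, config$lead_time_range[1], config$lead_time_range[2])
      eligible_onsets <- t3[t3 + config$lead_time_range[2] <= config$followup_months]
      onset <- sample(eligible_onsets, 1)
      clinical_relapse_month <- onset + lead_time
    }

    baseline_fraction <- min(
      rlnorm(
        1,
        log(config$blood_vaf_mean_baseline) - config$blood_vaf_sdlog^2 / 2,
        config$blood_vaf_sdlog
      ),
      0.5
    )
    germline_artifact <- runif(1) < config$germline_artifact_prob

    variants <- simulate_variant_profile(config, pid)
    trajectory <- simulate_trajectory(
      config, schedule, baseline_fraction, clinical_relapse_month, lead_time
    )

    # Realized draws: compliance thinning; draws scheduled at or after
    # clinical relapse collapse to a single relapse draw labelled T4.
    kept <- runif(nrow(schedule)) < config$draw_compliance
    draws <- trajectory[kept, , drop = FALSE]
    if (relapse) {
      draws <- draws[draws$month < clinical_relapse_month, , drop = FALSE]
      if (runif(1) < config$draw_compliance) {
        draws <- dplyr::bind_rows(draws, tibble::tibble(
          timepoint = "T4", month = clinical_relapse_month,
          true_fraction = config$relapse_max_fraction
        ))
      }
    } else {
      draws <- draws[draws$month <= config$followup_months, , drop = FALSE]
    }

    has_t0 <- "T0" %in% draws$timepoint
    has_post_surgery <- any(draws$month >= config$surgery_month)
    category_truth <- if (germline_artifact) {
      "germline_artifact"
    } else if (!has_t0 || !has_post_surgery) {
      "insufficient_data"
    } else if (baseline_fraction < config$low_baseline_threshold) {
      "low_baseline_signal"
    } else {
      "evaluable"
    }

    tibble::tibble(
      patient_id = pid,
      pcr = pcr,
      relapse = relapse,
      surgery_month = config$surgery_month,
      clinical_relapse_month = clinical_relapse_month,
      molecular_onset_month = onset,
      lead_time_truth = lead_time,
      baseline_fraction = baseline_fraction,
      germline_artifact = germline_artifact,
      last_followup_month = if (relapse) clinical_relapse_month else config$followup_months,
      category_truth = category_truth,
      variants = list(variants),
      trajectory = list(trajectory),
      draws = list(draws)
    )
  })

  out <- dplyr::bind_rows(records)
  class(out) <- c("mrd_cohort", class(out))
  attr(out, "config") <- config
  out
}

#' Simulate template-level panel measurements for a cohort
#'
#' Converts true plasma fractions into per-locus consensus read counts
#' without simulating individual reads: at each realized draw and panel
#' locus the alt-template count is Binomial(`templates`, allele fraction),
#' background substitution error contributes Binomial(`templates`,
#' `background_error`) additional alt calls, and raw (pre-consensus)
#' coverage is `templates` times the mean read-family size. This is the
#' distribution the UMI consensus path recovers from reads, which makes
#' cohort-scale monitoring runs cheap; the read-level path
#' ([simulate_amplicon_reads()]) is exercised at desk scale.
#'
#' A germline-artifact patient has one panel locus measured near 100% VAF at
#' every draw.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param panels Panel designs from [design_cohort_panels()] /
#'   [select_panel()].
#' @param templates Unique templates (consensus depth) per amplicon.
#' @param background_error Per-template probability of a spurious alt call
#'   after consensus.
#' @param mean_family_size Mean reads per UMI family (sets raw coverage).
#' @param probe_fail_prob Probability a probe underperforms at a draw (its
#'   raw coverage is drawn below 1,000x so the probe-QC rule fires).
#' @return A long tibble of locus read counts, one row per
#'   patient x draw x panel locus.
#' @export
simulate_measurements <- function(cohort, panels,
                                  templates = 20000,
                                  background_error = 1e-5,
                                  mean_family_size = 4,
                                  probe_fail_prob = 0) {
  config <- attr(cohort, "config")
  purrr::pmap(
    list(cohort$patient_id, cohort$draws, cohort$germline_artifact),
    function(pid, draws, germline) {
      panel <- panels[panels$patient_id == pid, , drop = FALSE]
      if (nrow(panel) == 0 || nrow(draws) == 0) {
        return(NULL)
      }
      germline_locus <- if (germline) panel$pos[1] else NA_real_
      tidyr::crossing(
        draws[, c("timepoint", "month", "true_fraction")],
        panel[, c("chrom", "pos", "ref_allele", "alt_allele", "gene_symbol", "amplicon_id")]
      ) |>
        dplyr::mutate(
          patient_id = pid,
          af = dplyr::if_else(
            !is.na(germline_locus) & .data$pos == germline_locus,
            0.998, pmin(.data$true_fraction, 1)
          ),
          consensus_depth = as.integer(templates),
          alt_count = rbinom(dplyr::n(), templates, .data$af) +
            rbinom(dplyr::n(), templates, background_error),
          alt_count = pmin(.data$alt_count, templates),
          no_call_count = 0L,
          other_count = 0L,
          ref_count = templates - .data$alt_count,
          raw_coverage = dplyr::if_else(
            runif(dplyr::n()) < probe_fail_prob,
            as.integer(round(runif(dplyr::n(), 0, 999))),
            as.integer(round(templates * mean_family_size))
          )
        ) |>
        dplyr::select(
          "patient_id", "timepoint", "month", "amplicon_id", "chrom", "pos",
          "ref_allele", "alt_allele", "gene_symbol",
          "ref_count", "alt_count", "other_count", "no_call_count",
          "consensus_depth", "raw_coverage"
        )
    }
  ) |>
    dplyr::bind_rows()
}
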