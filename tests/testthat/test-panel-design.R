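test_that("each filter criterion removes exactly its offenders", {
  v <- make_variants(6,
    population_af = c(0, 0.05, 0, 0, 0, 0),
    depth = c(100, 100, 5, 100, 100, 100),
    mq0_fraction = c(0, 0, 0, 0.5, 0, 0),
    known_variant = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    confidence = c("high", "high", "high", "high", "high", "low")
  )
  kept <- filter_variants(v)
  expect_equal(kept$pos, v$pos[1])

  # Disabling a criterion restores its victims.
  kept2 <- filter_variants(v, filter_config(exclude_known = FALSE))
  expect_true(v$pos[5] %in% kept2$pos)

  # Order preserved, empty in/out, idempotence.
  expect_identical(filter_variants(v[0, ]), v[0, ])
  expect_identical(filter_variants(kept), kept)
})

test_that("records with missing covariates are rejected with a message", {
  v <- make_variants(2)
  v$depth[2] <- NA
  expect_message(kept <- filter_variants(v), "missing filter covariates")
  expect_equal(nrow(kept), 1)
})

test_that("panel selection anchors non-silent TP53 and supplements by VAF", {
  # TP53 missense at low VAF plus four higher-VAF passengers.
  v <- make_variants(5,
    gene_symbol = c("TP53", "PIK3CA", "PTEN", "RB1", "NF1"),
    consequence_class = c("missense", rep("missense", 4)),
    tissue_vaf = c(0.12, 0.40, 0.35, 0.30, 0.25)
  )
  panel <- select_panel(v)
  expect_setequal(panel$gene_symbol, c("TP53", "PIK3CA", "PTEN", "RB1"))
  expect_equal(nrow(panel), 4)

  # Two TP53 anchors plus two passengers fill a target of 4.
  v2 <- make_variants(4,
    gene_symbol = c("TP53", "TP53", "PIK3CA", "PTEN"),
    consequence_class = c("missense", "nonsense", "missense", "missense"),
    tissue_vaf = c(0.20, 0.05, 0.40, 0.30)
  )
  expect_setequal(select_panel(v2)$gene_symbol, c("TP53", "TP53", "PIK3CA", "PTEN"))

  # A silent TP53 variant is not an anchor; it competes on VAF alone.
  v3 <- make_variants(1,
    gene_symbol = "TP53", consequence_class = "silent", tissue_vaf = 0.5
  )
  panel3 <- select_panel(v3)
  expect_equal(nrow(panel3), 1)
  expect_identical(panel3$consequence_class, "silent")

  expect_error(select_panel(make_variants(0)), class = "mrdtrace_panel_error")
})

test_that("panel selection is order-independent and respects size bounds", {
  set.seed(43)
  cfg <- cohort_config(seed = 43)
  for (i in 1:15) {
    v <- simulate_variant_profile(cfg, "P")
    v <- filter_variants(v)
    if (nrow(v) == 0) next
    panel <- select_panel(v)
    shuffled <- select_panel(v[sample(nrow(v)), ])
    expect_setequal(panel$pos, shuffled$pos)
    expect_gte(nrow(panel), 1)
    expect_lte(nrow(panel), 6)
    # Variant loci sit strictly inside their amplicons.
    expect_true(all(
      panel$pos - 1 > panel$amplicon_start & panel$pos - 1 < panel$amplicon_end - 1
    ))
  }
})

test_that("mean panel size on a default synthetic cohort is about 4 amplicons", {
  co <- simulate_cohort(cohort_config(n_patients = 60, seed = 47))
  panels <- suppressMessages(design_cohort_panels(co))
  mean_size <- nrow(panels) / length(unique(panels$patient_id))
  expect_gte(mean_size, 3.5)
  expect_lte(mean_size, 4.5)
})

test_that("pool layout is first-fit, patient-coherent and capacity-bounded", {
  # 50 panels totalling 208 primer pairs, as in a full cohort design.
  sizes <- c(rep(4, 42), rep(5, 6), rep(6, 1), 4)
  stopifnot(sum(sizes) == 208)
  panels <- purrr::map2(sprintf("PT%02d", seq_along(sizes)), sizes, function(p, s) {
    make_variants(s, patient_id = p) |>
      dplyr::mutate(
        amplicon_id = sprintf("%s_a%d", p, seq_len(s)),
        primer_pair_id = sprintf("%s_pp%d", p, seq_len(s))
      )
  }) |>
    dplyr::bind_rows()
  laid <- build_pools(panels)

  per_pool <- table(laid$pool_id)
  expect_true(all(per_pool <= 100))
  # Brute-force check: every patient's pairs occupy exactly one pool.
  by_patient <- tapply(laid$pool_id, laid$patient_id, function(x) length(unique(x)))
  expect_true(all(by_patient == 1))
  # 208 pairs cannot fit in two pools of 100.
  expect_gte(length(per_pool), 3)
  expect_equal(sum(per_pool), 208)

  # Single panel of 6 in one pool; empty layout passes through.
  single <- panels[panels$patient_id == "PT49", ]
  expect_equal(unique(build_pools(single)$pool_id), "pool01")
  expect_equal(nrow(build_pools(panels[0, ])), 0)

  # A panel larger than the cap is impossible to lay out.
  expect_error(
    build_pools(panels, panel_config(max_primer_pairs_per_pool = 3)),
    class = "mrdtrace_layout_error"
  )
})

test_that("germline BRCA flagging follows the classification table", {
  gv <- tibble::tibble(
    patient_id = c("A", "A", "B", "C", "D"),
    chrom = "chr17",
    pos = c(100, 200, 300, 400, 500),
    ref_allele = "A",
    alt_allele = "T",
    gene_symbol = c("BRCA1", "KRAS", "BRCA2", "TP53", "BRCA1")
  )
  ct <- tibble::tibble(
    chrom = "chr17",
    pos = c(100, 300, 500, 500),
    ref_allele = "A",
    alt_allele = "T",
    classification = c("Pathogenic", "Likely pathogenic", "Pathogenic", "Benign")
  )
  status <- flag_brca_germline(gv, ct)
  expect_identical(
    status$brca_status[match(c("A", "B", "C", "D"), status$patient_id)],
    c("positive_BRCA1", "positive_BRCA2", "negative", "indeterminate")
  )

  # Malformed table rows are rejected with a message.
  ct_bad <- dplyr::bind_rows(ct, tibble::tibble(
    chrom = "chr17", pos = NA_real_, ref_allele = "A", alt_allele = "T",
    classification = "Pathogenic"
  ))
  expect_message(flag_brca_germline(gv, ct_bad), "malformed")
})
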