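# Test helpers: small fixture builders and independent brute-force oracles.

# Minimal well-formed somatic variant rows with overridable fields.
make_variants <- function(n = 1, ...) {
  defaults <- tibble::tibble(
    patient_id = "P1",
    chrom = "chr1",
    pos = seq_len(n) * 1000,
    ref_allele = "A",
    alt_allele = "T",
    gene_symbol = "PIK3CA",
    consequence_class = "missense",
    tissue_vaf = 0.3,
    depth = 100,
    population_af = 0,
    mq0_fraction = 0,
    known_variant = FALSE,
    confidence = "high"
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# A panel row with concrete amplicon context for read simulation.
make_test_panel <- function(n_amplicons = 1, flank = 75) {
  v <- make_variants(n_amplicons,
    pos = seq_len(n_amplicons) * 10000 + flank + 1
  )
  p <- v |>
    dplyr::mutate(
      amplicon_start = pos - 1L - flank,
      amplicon_end = pos + flank,
      amplicon_id = sprintf("P1_amp%02d", seq_len(n_amplicons)),
      primer_pair_id = sprintf("P1_pp%02d", seq_len(n_amplicons))
    )
  build_amplicon_sequences(p)
}

# Exhaustive clustering oracle for directional UMI grouping: connected
# components of the graph whose edges join N-free UMI pairs at Hamming
# distance <= max_dist with min(count) <= max(count)/2 + 1. O(n^2) flood
# fill, independent of the package's neighbour-hash implementation.
oracle_cluster_umis <- function(umis, counts, max_dist = 1) {
  n <- length(umis)
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  has_n <- grepl("N", umis, fixed = TRUE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (has_n[i] || has_n[j]) next
      if (ham(umis[i], umis[j]) <= max_dist &&
        min(counts[i], counts[j]) <= max(counts[i], counts[j]) / 2 + 1) {
        adj[i, j] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    next_id <- next_id + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- next_id
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0), which(!is.na(comp)))
    }
  }
  comp
}

# Canonical partition representation for comparing clusterings.
partition_key <- function(umis, labels) {
  parts <- split(sort(umis), labels[order(umis)])
  paste(sort(vapply(parts, paste, "", collapse = ",")), collapse = "|")
}

# Write a minimal VCF 4.2 encoding of a variant tibble (test fixture
# builder; the package only reads this format).
write_test_vcf <- function(variants, path) {
  info <- sprintf(
    "PATIENT=%s;GENE=%s;CLASS=%s;TVAF=%s;DP=%s;PAF=%s;MQ0F=%s;KNOWN=%s;CONF=%s",
    variants$patient_id, variants$gene_symbol, variants$consequence_class,
    variants$tissue_vaf, variants$depth, variants$population_af,
    variants$mq0_fraction, as.integer(variants$known_variant), variants$confidence
  )
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tissue VAF\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=PAF,Number=1,Type=Float,Description=\"Population AF\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"MQ0 fraction\">",
    "##INFO=<ID=KNOWN,Number=1,Type=Integer,Description=\"Known variant\">",
    "##INFO=<ID=CONF,Number=1,Type=String,Description=\"Call confidence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
      variants$chrom, variants$pos, variants$ref_allele, variants$alt_allele, info
    )
  )
  writeLines(lines, path)
  path
}

# Fabricate an mrd_monitor-shaped tibble for summary-level tests.
make_monitor <- function(n, category = "evaluable", pcr = FALSE,
                         ever_positive = FALSE, in_denom = FALSE,
                         detected = FALSE, lead = NA_real_) {
  empty_calls <- tibble::tibble(
    timepoint = character(0), month = numeric(0), positivity = character(0)
  )
  tibble::tibble(
    patient_id = sprintf("M%03d", seq_len(n)),
    pcr = rep_len(pcr, n),
    category = rep_len(category, n),
    category_reason = "",
    clinical_relapse_month = NA_real_,
    molecular_relapse_month = NA_real_,
    lead_time_months = rep_len(lead, n),
    ever_positive_remission = rep_len(ever_positive, n),
    in_sensitivity_denominator = rep_len(in_denom, n),
    detected = rep_len(detected, n),
    positivity = rep(list(empty_calls), n)
  )
}
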