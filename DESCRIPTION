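Package: mrdtrace
Title: Tumor-Informed ctDNA Micro-Panel Design and Molecular Relapse Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a personalized circulating tumor DNA (ctDNA)
    minimal-residual-disease monitoring workflow for tumor-informed amplicon
    micro-panels: somatic variant filtering and per-patient panel selection
    (all non-silent TP53 variants plus top-VAF supplements), UMI-based read
    family grouping and molecular consensus error correction with read-error,
    base-error and no-call filters, allele counting and variant allele
    fraction (VAF) quantification with probe-level coverage QC, longitudinal
    positivity calling (VAF > 0.005%), patient evaluability classification,
    molecular-relapse detection with lead-time estimation, and the cohort
    statistics used in such studies (uncorrected Pearson chi-square on the
    pCR-by-positivity table, exact Clopper-Pearson binomial bounds,
    tissue/blood concordance). A seeded synthetic-cohort generator emulates
    the statistical structure of a neoadjuvant triple-negative breast cancer
    monitoring study (variant burden, TP53 prevalence, tissue and plasma VAF
    scales, draw schedules, relapse lead times, UMI read families) so every
    stage is testable at desk scale with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
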