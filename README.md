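# mrdtrace

Tumor-informed ctDNA micro-panel design and molecular-relapse (MRD)
monitoring in R.

## Who this is for

Translational genomics groups that track minimal residual disease in
solid tumors (the motivating setting is neoadjuvant-treated
triple-negative breast cancer) with **personalized amplicon micro-panels**:
a handful of patient-private somatic variants from baseline tumor/normal
exomes, assayed deeply in serial plasma draws with UMI-based error
correction. The package implements the full analysis chain — panel
selection, UMI consensus, VAF quantification, positivity calling,
evaluability classification, relapse detection and cohort statistics —
plus a seeded synthetic-cohort generator with complete ground truth, so
the chain is testable end to end without controlled-access patient data.

## The method in brief

* **Panel design.** Somatic variants are filtered on five criteria
  (known sites, population AF, MQ0 fraction, depth, confidence); each
  panel takes every non-silent *TP53* variant plus up to three further
  variants with the highest tissue VAF, 1–6 amplicons total (target 4),
  laid out first-fit into ≤100-primer-pair pools.
* **UMI consensus.** The UMI is the first 10 bp of read 2. Families
  (UMIs within Hamming distance 1, merged under the directional rule
  `min ≤ max/2 + 1`) collapse to per-position plurality consensus; reads
  with error rate > 5% are dropped, bases with error > 10% masked to N,
  reads with > 50% no-calls dropped; samples need mean unique coverage
  ≥ 500.
* **Monitoring.** VAF = alt/(ref+alt+other) per locus; probes under
  1,000× raw coverage are excluded. A draw is positive when any panel
  variant has VAF > 0.005% (5 × 10⁻⁵). The earliest positive draw at or
  after surgery (relapse-confirmation draws excluded) is the molecular
  relapse; lead time = clinical − molecular relapse month.
* **Statistics.** Uncorrected Pearson chi-square (Σ(O−E)²/E, 1 df) for
  the pCR × ever-positivity 2×2; exact Clopper–Pearson binomial bounds
  (bisection on the binomial tails) for detection sensitivity;
  tissue/blood variant concordance.

## Worked example

```r
library(mrdtrace)

# Exact sensitivity bound used to plan a 50-patient cohort:
clopper_pearson(9, 10)
#> Exact binomial CI: 9/10 = 0.900, 95% CI [0.5550, 0.9975]

# Association between remission positivity and pCR (1/8 vs 8/17):
pearson_chi2(matrix(c(1, 8, 7, 9), 2))
#> Pearson chi-square (df = 1): X^2 = 2.8199, p = 0.0931

# A small synthetic cohort, end to end:
res <- run_pipeline(cohort_config(n_patients = 12, seed = 7), templates = 5000)
res$summary
#> ctDNA monitoring summary (12 patients)
#>   evaluable            8
#>   insufficient_data    3
#>   low_baseline_signal  1
#>   germline_artifact    0
#> Relapse detection: 1/1 (100%), 95% CI lower 2.5%
#> Mean lead time: 4.8 months
#> pCR association: ever-positive 50% (pCR) vs 67% (no pCR), chi-square p = 0.673
```

The first two calls reproduce published worked statistics exactly: a
9-of-10 detection rate has an exact lower 95% confidence limit of 55%,
and the uncorrected chi-square on the printed 2×2 gives p ≈ 0.093
(printed as 0.10). The synthetic run shows the cohort readout: 8 of 12
patients are evaluable (3 lack baseline or post-surgery draws under the
80% draw-compliance default, 1 has baseline VAF below the 0.05%
detectability floor), the single eligible relapse is caught 4.8 months
before its clinical relapse, and the pCR association on a 12-patient toy
cohort is, as expected, uninformative. `glance(res$summary)` returns the
same numbers as a one-row tibble; `autoplot(res$summary)` draws the
per-timepoint positivity grid and `plot_patient_timeline()` a patient's
VAF trajectory.

`vignettes/mrd-monitoring.Rmd` documents the models, parameter defaults,
numerical conventions and limitations.

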