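---
title: "Tumor-informed micro-panel MRD monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed micro-panel MRD monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdtrace)
library(dplyr)
```

## The problem

After neoadjuvant chemotherapy and surgery for triple-negative breast
cancer, a large fraction of patients are in clinical remission yet some
harbor minimal residual disease (MRD) that later resurfaces as overt
relapse. Circulating tumor DNA (ctDNA) offers a molecular window on that
residual disease: tumor-derived fragments in plasma carry the somatic
variants of the tumor, at allele fractions orders of magnitude below what
standard sequencing error rates allow to call. `mrdtrace` implements a
tumor-informed monitoring workflow built around three ideas:

1. **Personalized micro-panels.** Whole-exome calls from the baseline
   tumor/normal pair define each patient's private somatic variants; a
   small panel (1–6 amplicons, aiming at 4) is designed per patient,
   anchored on non-silent *TP53* variants and topped up with the
   highest-VAF remaining variants.
2. **UMI consensus error correction.** Each original template molecule is
   tagged with a unique molecular identifier (the first 10 bp of read 2).
   Reads sharing a UMI are a *read family*; collapsing a family to its
   per-position plurality base cancels independent sequencing errors and
   leaves roughly one consensus read per input molecule, pushing the
   effective error rate low enough to quantify VAFs in the 0.005–0.05%
   range.
3. **Longitudinal positivity calling.** Plasma drawn at baseline (T0),
   early in therapy (T1, Cycle 1 Day 3), at surgery (T2) and during
   surveillance (T3.*k*; a relapse-confirmation draw is labelled T4) is
   quantified at the panel loci. A timepoint is *positive* when any panel
   variant exceeds VAF 0.005%; the earliest positive monitoring draw at or
   after surgery is the *molecular relapse*, and its distance to clinical
   relapse is the *lead time*.

Everything is driven by a synthetic-cohort generator with full ground
truth, so each stage is verifiable at desk scale without controlled-access
patient data.

## Cohort model and generator defaults

`cohort_config()` encodes the study conditions the generator emulates.
The defaults are fixed once and are not tuning knobs:

| Parameter | Default | Why |
|---|---|---|
| `n_patients` | 50 | translational cohort size |
| `relapse_rate` | 0.14 | 7/50 clinical relapses |
| `pcr_rate` | 0.34 | 17/50 pathological complete responses |
| `variant_count_meanlog` | log 77.5 | per-tumor somatic burden, median 77.5 |
| `variant_count_sdlog` | 1.4 | places the clipped range [1, 1970] within reach of a 50-patient draw while keeping the median at 77.5; reproduces the observed heavy right tail (occasional >750-variant hypermutators) |
| `tp53_prob` | 0.86 | fraction of tumors with a non-silent *TP53* variant |
| `tissue_vaf_mean` | 0.329 | mean tumor-tissue VAF; Beta-distributed with concentration 10 |
| `blood_vaf_mean_baseline` | 0.0033 | mean baseline plasma VAF; log-normal with `sdlog` 1 so that a realistic minority (~8%) of patients fall below the 0.05% detectability floor |
| `surgery_month` | 5 | six 21-day cycles plus 3–5 weeks to surgery |
| `draw_interval_months` | 6 | surveillance every 3–6 months; the upper bound is used as the nominal schedule |
| `draw_compliance` | 0.8 | blood-draw compliance was a major loss source in practice; 0.8 yields an insufficient-data fraction comparable to a third of the cohort |
| `lead_time_range` | [2, 7] | months by which molecular onset precedes clinical relapse |
| `relapse_onset_fraction` | 0.002 | plasma tumor fraction when the signal reappears (40× the positivity threshold), growing ×1.6/month to a 5% cap |
| `c1d3_multiplier` | 1.5 | early-treatment DNA release at Cycle 1 Day 3; a free parameter, not an inferred quantity, since the between-draw kinetics before surgery are not constrained by the data the model emulates |
| `germline_artifact_prob` | 0.04 | 2/50 patients whose panel contained an apparent germline variant (~100% plasma VAF) |

Relapse construction: a molecular onset month is placed **on a scheduled
surveillance draw**, a lead time is drawn uniformly from [2, 7] months,
and clinical relapse follows `onset + lead`. This matches the narrative
shape of observed relapse trajectories (a VAF spike at a scheduled draw,
*k* months before clinical relapse) and makes detection well-posed: with
compliant draws the first truly positive draw *is* the onset draw, so
recovered lead times can be compared to truth. A lead time that would
reach back past surgery is clamped to the surgery draw, which models
persistent residual disease rather than re-emergence.

Outcome assignments (pCR, relapse) are independent Bernoulli draws.
Non-relapse patients — pCR or not — carry exactly zero tumor signal after
surgery; remission-phase positives in non-relapse patients therefore arise
only from background error. Real cohorts show unexplained remission
positives beyond that; reproducing their rate is outside what this
generator claims to emulate.

### Two measurement paths

The generator emits measurements at two granularities:

* **Template level** (`simulate_measurements()`): per locus and draw,
  alt-template counts are Binomial(templates, allele fraction), plus a
  Binomial background at `background_error` (default `1e-5` per template),
  with raw coverage set to templates × mean family size. This is the
  distribution the read path recovers at low error, and it makes
  cohort-scale runs (50 patients × ~10 draws × 4 loci at 20,000
  templates) essentially free.
* **Read level** (`simulate_amplicon_reads()` →
  `collapse_and_count()`): actual UMI-tagged read pairs with per-base
  substitution/no-call noise, run through the full UMI/consensus stack.
  Used at desk scale (hundreds to a few thousand templates), where
  zero-noise runs are asserted to round-trip *exactly* to the recorded
  template truth.

The package's correctness argument composes the two: the read path is
exact at desk scale, and the template path is the read path's limiting
distribution, verified where they overlap.

## Panel design

`filter_variants()` applies five exclusion criteria (known variants, high
population allele frequency, high MQ0 fraction, low depth, low
confidence). The criteria are fixed; the numeric thresholds (0.001, 0.10,
20×) are conventional somatic-filtering defaults, exposed in
`filter_config()` because no canonical values exist for them.

`select_panel()` implements the selection heuristic as a deterministic,
order-independent function: all non-silent *TP53* variants are anchored
(silent *TP53* variants compete on VAF like any other variant), then
supplements are added by descending tissue VAF until
`min(target_size, available)`, never exceeding 6, with ties broken by
higher depth then ascending (chrom, pos). Two genuinely open corners were
closed as follows and are configurable: when *TP53* anchors alone exceed
the panel cap the top-VAF six are kept, and when a patient has no
non-silent *TP53* variant the panel is simply filled to `target_size` by
VAF (the "up to three supplements" cap applies only when anchors exist).
Amplicons are a fixed ±75 bp window around the locus — primer
thermodynamics are out of scope, but coordinates must be concrete —
stored 0-based half-open internally and exported 1-based.
`build_pools()` packs panels first-fit into ≤100-primer-pair pools,
keeping each patient's pairs together.

A patient whose variants all fail filtering gets no panel and drops out
of monitoring with a warning; such patients correspond to the
"insufficient biomarkers" stratum of real cohorts.

## UMI consensus

* **Grouping** (`group_families()`): within an amplicon, UMIs within
  Hamming distance 1 merge under the directional count rule (the smaller
  count must be ≤ larger/2 + 1), computed as connected components of the
  qualifying-edge graph via single-substitution neighbour hashing. This
  is the standard way to separate PCR/sequencer error satellites of an
  abundant UMI from genuinely co-occurring templates. UMIs containing N
  never merge except with exact duplicates. Setting
  `umi_edit_distance = 0` gives exact grouping — which the exactness
  tests use, because with random 10-mers two *distinct* templates can
  legitimately sit at distance 1 and directional merging would (rarely
  but correctly, per its rule) fuse them.
* **Consensus** (`call_consensus()`): per-position plurality among non-N
  member bases; ties and all-N columns yield N. The per-position error is
  the fraction of non-N member bases disagreeing with the called
  consensus; the read error rate aggregates disagreements over called
  positions. A count-based (rather than quality-weighted) consensus is
  used deliberately: the filter thresholds are stated as error *rates*,
  counts are reproducible, and the simulator emits constant Q30 qualities.
* **Filters** (`filter_consensus()`): strictly in this order — drop reads
  with error rate > 5%, mask positions with error > 10% to N, drop reads
  that are then > 50% no-calls. The order matters (a read dropped at step
  1 is never masked) and follows the order in which the rules are stated.
  All three thresholds are strict (">"), matching "exceeded"; the
  sample-level QC floor of mean unique coverage 500 is inclusive (≥),
  matching "minimum of".

## Quantification and monitoring

`count_alleles()` lets each passing consensus read vote once at the locus
(ref/alt/other/N); `compute_vaf()` uses VAF = alt/(ref+alt+other) — no
denominator definition is canonical, and excluding no-calls means masked
bases neither support nor dilute the variant. The low-performing-probe
rule fails probes with raw (pre-consensus) observed coverage < 1,000×;
raw rather than consensus coverage is used because consensus coverage is
already governed by the separate 500× QC, and both are recorded so the
rule can be re-targeted. Failed-probe measurements are retained but
excluded from positivity.

`call_positivity()` is strict (VAF > 5 × 10⁻⁵). Note the interaction
with depth: below 20,000 evaluable consensus reads, a single alt read
exceeds the threshold, so specificity rests on probe QC and on
`min_positive_variants` (default 1, the published rule; 2 is the
conservative alternative). With the default background error of 1e-5 per
template this produces occasional pre-onset false positives in long
monitoring courses — visible as inflated apparent lead times in
cohort-scale runs — which mirrors the single-variant positives such
assays treat with suspicion. The end-to-end signal-recovery property is
therefore assessed under a clean background, and the default behaviour is
reported as-is.

Classification precedence is germline artifact (any panel variant ≥ 90%
plasma VAF) → insufficient data (no baseline, no evaluable baseline, or
no post-surgery draw) → low baseline signal (all baseline VAFs < 0.05%)
→ evaluable. The evaluable/low-baseline boundary is applied to *measured*
baseline VAF; patients whose true baseline sits near 0.05% can land on
either side under binomial sampling, which the tests accommodate
explicitly.

Monitoring window: `[surgery, clinical relapse)`. Baseline or C1D3
positivity never triggers molecular relapse; the T4 relapse-confirmation
draw neither triggers it nor counts toward the remission ever-positive
flag. Detection sensitivity is computed over relapsed patients with at
least one monitoring draw within 6 months before clinical relapse — the
others' relapses were unobservable under their draw schedule. Patients
lost to follow-up are summarized at their censoring month; nothing is
imputed.

## Statistics

* `pearson_chi2()` computes Σ(O−E)²/E on 1 df, uncorrected by default: on
  the 2×2 of ever-positivity by pCR (1/8 vs 8/17) the uncorrected
  statistic is 2.82 (p = 0.093, consistent with the reported p = 0.10)
  whereas the Yates correction would give p ≈ 0.22; the correction is a
  flag, not the default.
* `clopper_pearson()` solves the exact binomial tail equations by
  bisection to 10⁻¹⁰ rather than through a Beta-quantile identity, so the
  implementation is self-contained and its defining equations are
  directly checkable by binomial summation (the tests do exactly that for
  all x ≤ n ≤ 30, and verify coverage ≥ nominal by enumeration for
  n ≤ 15). Observing 9/10 relapses detected gives a lower 95% bound of
  55.0%, the planning bound for a 50-patient cohort.
* Percentages render half-up, keeping a decimal only when exact at that
  decimal (12.5% from 1/8; 47% from 8/17; 82% from 27/33); means round
  half-up to one decimal (mean of 7, 3, 5, 2 months → 4.3).

## Problem sizes

The shipped tests and the acceptance script choose sizes so that every
property is measured with real power yet the whole suite stays
interactive: exact round trips at 400–1,000 templates; error suppression
at 1,100 families × 151 bp (> 10⁵ consensus bases at per-base error 2%,
asserting a residual < 0.2%); grouping equivalence against an exhaustive
O(n²) oracle at ≤ 20 UMIs × 70 cases; cohort monitoring at 50 patients ×
20,000 templates through the template-level path. Production-scale depth
(~6 × 10⁶ read pairs per library) is reachable through the same
configuration objects but is not what the tests claim to have measured.

## A worked run

```{r demo, eval = FALSE}
cfg <- cohort_config(n_patients = 12, seed = 7)
res <- run_pipeline(cfg, templates = 5000)
glance(res$summary)
autoplot(res$summary)
plot_patient_timeline(res$timeline, res$timeline$patient_id[1])
```

## Known limitations

* UMI barcodes are simulated collision-free; real random 10-mers collide
  at high template counts, biasing consensus depth slightly downward.
* Indel alleles are carried as annotations and matched as full allele
  strings; the read simulator itself emits substitutions only.
* No duplex (double-strand) consensus, base-quality weighting, or
  background-error modeling beyond the consensus filters.
* The generator does not couple relapse to pCR status, does not model
  unexplained remission positives, copy-number signal, or clinical
  covariates beyond pCR/relapse — cohort-level association numbers from
  synthetic runs characterize the pipeline, not the disease.
* Survival modeling (Kaplan–Meier, Cox) is out of scope; the monitoring
  summary stops at detection, lead times and the 2×2 association.
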