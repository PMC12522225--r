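---
title: "Screening for esophageal lesions from cfDNA end motifs and protein markers"
author: "cfMotifScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for esophageal lesions from cfDNA end motifs and protein markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfMotifScreen)
```

# The problem and the model

Esophageal squamous cell carcinoma (ESCC) is usually diagnosed late; its
precancerous lesions (low- and high-grade intraepithelial neoplasia, LGIN
and HGIN) and early-stage tumours are curable endoscopically, which makes a
non-invasive triage test valuable. Two blood-borne signals carry usable
information. First, plasma cell-free DNA (cfDNA) is fragmented by
nucleases whose cleavage preferences change in cancer, so the *terminal
4-mer end motif* spectrum of cfDNA fragments shifts between patients and
controls. Second, a panel of serum tumour protein markers (AFP, CA19-9,
CA24-2, CA72-4, CEA, Cyfra21-1, SCC, pepsinogens I and II, and the derived
ratio PGR = PG I / PG II) shows group-level concentration shifts.

This package implements the full analysis as a reusable, tested pipeline:

1. **End-motif profiling.** Properly-paired, primary, non-duplicate
   fragments with MAPQ ≥ 30 and template length in [50, 500] bp are counted
   into the 256 lexicographically ordered 4-mers. By default both fragment
   ends contribute: the reference 4-mer at the left terminus read 5'→3' on
   the forward strand, and the reverse complement of the reference 4-mer at
   the right terminus (the 5' end of the reverse strand). Counts become
   *ratio-to-average* values, $r_m = c_m / (\sum_m c_m / 256)$, so every
   usable sample's profile averages exactly 1, and are then Z-scored per
   motif with statistics fitted on the training split only.

2. **Differential selection and reduction.** Per-motif two-sample
   Student t-tests compare cases (ESCC ∪ ESPL) against controls; motifs
   with raw two-sided p < 0.05 are kept, with up/down direction given by
   the sign of the case-minus-control mean. PCA (fitted on training data,
   default 30 components, deterministic sign convention) compresses the
   selected motifs.

3. **Classifiers.** Three random-forest recipes: *motif* (principal
   components), *protein* (the ten marker features), and *combined*
   (components plus markers). Each recipe runs random-forest recursive
   feature elimination (RF-RFE, step 1) scored by mean AUC over shared
   stratified 10-fold cross-validation, then fits the final forest on the
   chosen subset.

4. **Evaluation.** AUC (Mann–Whitney form) with DeLong variance and CIs,
   paired DeLong comparison of correlated AUCs, Youden-index thresholds
   fixed on the validation split, sensitivity/specificity with Wald CIs
   overall and per lesion subgroup, confusion matrices, and single-marker
   threshold classifiers. Baseline comparability across splits uses
   Pearson chi-square (categorical) and Kruskal–Wallis (numeric)
   statistics.

# A worked run on a synthetic cohort

Patient-level data for this design are not publicly available, so the
package ships a seeded generator that emulates the cohort structure the
analysis assumes (three groups over eight subgroups, planted motif and
protein effects). Everything below is computed, not quoted.

```{r, eval = FALSE}
cfg <- simulationConfig(nPerSubgroup = twoArmCounts(200),
                        effectDelta = 0.3,
                        proteinParams = defaultProteinParams(1.5),
                        seed = 7)
run <- runPipeline(simConfig = cfg, seed = 7)
run
run$evaluations$combined$report
```

The run fits all three recipes on the training split, fixes each model's
operating threshold by the Youden index on the validation split, and
reports test-split AUCs, screening metrics and paired DeLong comparisons.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults define the study
conditions every property test runs under.

* **Cohort structure.** Subgroup sizes default to the reference cohort's
  composition (491 samples: 46 LGIN, 45 HGIN, 124 stage I, 23 II, 35 III,
  17 IV, 29 healthy, 172 benign); `twoArmCounts(n)` builds balanced
  two-arm cohorts with the same case mix. Demographics (age, sex, smoking,
  drinking) shift with group the way the reference cohort's do.
* **Motif model.** A fixed baseline probability vector over the 256 motifs
  is drawn once from a symmetric Dirichlet(50) under a frozen internal
  seed, so ground truth is identical across installs. A planted effect
  multiplies 75 "up" motifs by $e^{s\delta}$ and 128 "down" motifs by
  $e^{-s\delta}$ (then renormalises), where $\delta$ is `effectDelta`
  (default 0.3) and $s$ is a per-subgroup severity multiplier rising
  monotonically from 0.5 (LGIN) to 1.0 (stage IV) — emulating the
  clinical observation that sensitivity increases with progression.
  Per-sample probability vectors are Dirichlet draws around the subgroup
  mean (concentration 2000), and counts are multinomial given a
  negative-binomial fragment total (mean 50,000, size 20 — a desk-scale
  stand-in; real assays sequence orders of magnitude deeper).
* **Protein model.** Each marker is log-normal (all concentrations are
  positive; the source analysis reports no distributional detail) with
  multiplicative group shifts, by default >1 for CEA, Cyfra21-1, PG I and
  PG II in case groups.
* **What it does not emulate.** Real genome sequence, fragment-size
  spectra, GC bias, sequencing error, duplicates, batch effects, or
  realistic inter-marker correlation. Passing tests therefore demonstrate
  the *machinery* (no leakage, correct statistics, recoverable planted
  effects), not clinical performance on real plasma.

# Numerical and design choices

* **End convention.** "The last four bases of a fragment" is ambiguous;
  the default (5' terminal 4-mer of each strand, both ends counted)
  follows the dominant fragmentomics convention and doubles usable signal.
  `five_prime_left_only` and `three_prime_both_ends` reproduce the other
  readings. Motifs come from the reference, not read bases, so sequencing
  errors cannot perturb them; a soft-clipped terminus disqualifies that
  end, and windows containing N are skipped.
* **Z-score fitting population.** Statistics are fitted on the training
  split and frozen; fitting on all data would leak information into
  validation/test. Constant motifs map to z = 0 (flagged) rather than
  being dropped, keeping the 256-column geometry fixed for PCA.
* **Split sizes.** Fractions (0.49, 0.21, 0.30) are allocated by
  cumulative-floor quota: $n_i = \lfloor nF_i \rfloor - \lfloor nF_{i-1}
  \rfloor$ with $F_i$ the cumulative fractions. For $n = 491$ this yields
  exactly (240, 103, 148), the reference partition. (Per-fraction
  largest-remainder rounding would instead give 241/103/147.) Splits are
  stratified by subgroup by default, which keeps small synthetic cohorts
  balanced; strata under 3 samples fall back to a pooled draw with a
  warning.
* **t-test flavour.** Student's pooled-variance test by default (Welch by
  option); no multiplicity correction, matching the raw p < 0.05 filter
  of the source design (BH-FDR available but off).
* **RF-RFE.** The elimination criterion is impurity importance; subset
  scoring is mean fold AUC over folds shared across all subset sizes, so
  scores are comparable; ties break toward the smaller subset. Feature
  columns are canonicalised (sorted) on entry so the ranking is exactly
  invariant to input column order. The final forest uses 500 trees,
  √p variables per split, unlimited depth (no class weights); RFE forests
  use 250 trees. The reference analysis reports no forest
  hyperparameters; these are common defaults and are logged on the model.
  Feature counts the RFE arrives at (the reference analysis reports 16
  components, 8 proteins, 20 components + 6 proteins) are outcomes, never
  forced.
* **Youden threshold.** Candidates are midpoints between adjacent
  distinct scores plus ∓∞ sentinels; positive call iff score ≥ threshold.
  Ties in J break toward higher sensitivity (screening prefers not to
  miss cases), then lower threshold. Degenerate infinite optima are
  mapped, for reporting, to finite thresholds producing identical calls.
* **Proportion CIs.** Wald intervals clipped to [0, 100]% — this
  reproduces the published worked examples exactly (25/26 → 88.8–100%,
  10/11 → 73.9–100%); Wilson is available by flag. Chi-square tests are
  uncorrected for tables larger than 2×2, which matches all five
  published baseline statistics on recomputation.
* **DeLong machinery.** Variance and covariance come from structural
  components (placement values); degenerate paired comparisons (zero
  variance of the difference) report p = 1 when the AUC difference is 0
  and error otherwise.
* **Seeding.** One root seed fans out to per-stage seeds through a fixed
  integer recurrence; forests run single-threaded with explicit seeds, so
  a whole run is bit-stable on one platform.

# Problem sizes used by the test suite

The package's property tests run at desk scale, chosen to make the
statistical assertions well-powered while staying fast: oracle
equivalences at n ≤ 50 over ~1,000 seeded instances; DeLong calibration
at 100 samples per arm over 1,000 replicates; pipeline recovery and
null-calibration runs at 200 samples per arm over 5 seeds each, with
50,000 fragments per sample at the count level and ~3,000 fragments per
sample for alignment-file round trips. Null-calibration assertions are
made on the median AUC across replicates: a single null AUC at test-split
size ~120 has standard deviation ≈ 0.05, so per-replicate banding at
[0.4, 0.6] would reject a correct pipeline too often, while leakage — the
failure the check guards against — shifts the centre, which the median
detects.

# Limitations

* The synthetic generator is tuned for testability (clear planted
  effects), not biological fidelity; per-motif effect sizes in real ESCC
  plasma are unknown.
* Forest reproducibility is guaranteed on one platform, not across
  BLAS/compiler variants.
* Published cohort-level AUCs and sensitivities are not reproduction
  targets here: the underlying patient data are unavailable, so this
  package validates machinery against oracles, calibration, and planted
  truth instead.
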