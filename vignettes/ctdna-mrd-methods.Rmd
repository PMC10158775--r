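---
title: "Methods: tumor-informed ctDNA MRD calling and surveillance analytics"
author: "ctmrd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informed ctDNA MRD calling and surveillance analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmrd)
```

# The problem

After curative-intent resection of a solid tumor, a fraction of patients
carry microscopic residual disease that imaging cannot see. The residual
tumor sheds cell-free DNA into plasma; at typical postoperative burdens
the mutant allele fraction is well below 1%, so a targeted panel sequenced
to several thousand-fold effective depth observes single-digit mutant read
counts per site — the same order as sequencing error and as somatic
variants of blood-cell origin (clonal hematopoiesis, CHIP). `ctmrd`
implements the variant-level decision problem (which observed plasma
variants are credible tumor signals, and is this sample MRD-positive?) and
the cohort-level analytics built on top of serial samples.

The package consumes variant *calls* — per-site read counts with
annotations — not reads. Alignment, deduplication, UMI error polishing and
the upstream tumor-tissue variant calling are out of scope.

# Per-site error background

For each targeted SNV site the healthy-plasma panel provides, per sample
$i$, an error count $x_i$ out of depth $n_i$. The site model is
beta-binomial: $p \sim \mathrm{Beta}(\alpha, \beta)$,
$X \mid p \sim \mathrm{Bin}(n, p)$. We fit by the method of moments:

* pooled rate $\hat p = \sum x_i / \sum n_i$ (this *is* the stored
  `pooled_error_rate`, so the constraint
  $\alpha/(\alpha+\beta) = \hat p$ holds by construction);
* intra-class correlation $\hat\rho$ from the weighted dispersion of
  per-sample proportions around $\hat p$ (a Kleinman-style moment
  estimator), giving $\alpha + \beta = 1/\hat\rho - 1$, capped at
  $10^{10}$ — beyond the cap the tail is numerically binomial.

Sites with zero observed error get a pseudocount of 0.5 errors over the
pooled depth, so their test is proper rather than degenerate. Sites whose
pooled panel depth falls below `min_panel_depth` (default 300) get no
entry. A *fallback* entry is fitted across the per-site pooled counts:
across sites the error rate varies strongly (the generator draws it from
Beta(2, 19998), mean $10^{-4}$), and the cross-site fit captures that
variation for any site absent from the panel. A practical note from the
package's own simulations: at 500 samples × 3000× the *per-site*
dispersion signal is weak ($1 + \rho(n-1) \approx 1.15$), so per-site
shape parameters are noisy even though per-site rates are accurate to a
few percent; the cross-site fallback fit, pooling hundreds of sites, is
the reliable estimate of the generating shape parameters, and that is
what the parameter-recovery test asserts on.

The test is one-sided by design: only an *excess* of support reads over
the error background is evidence of ctDNA. For an observation with $s$
support reads at depth $n$,
$p\text{-value} = P(X \ge s)$ under the site's beta-binomial (fallback if
unseen), significant when below `alpha_level` (default 0.01, a config
parameter — the choice of level is a package default, stated rather than
inherited). Indels bypass the test entirely (the panel models SNVs only)
but obey every other filter. The test gates all plasma SNVs, tissue-derived
and private alike; both behaviors are switchable in `caller_config()`.

# The caller

Classification is tumor-informed and purely key-based: a plasma variant
whose exact `chrom:pos:ref:alt` key occurs in the patient's matched
tumor-tissue profile is *tissue-derived*; otherwise *ctDNA-private*.
Multi-allelic records and complex indels are matched by the same exact
key; no re-normalization is attempted, so both inputs must share one
left-alignment convention. Driver/hotspot flags recorded on the tissue
side are OR-ed onto matched plasma observations.

The filter cascade is fixed and fully logged, so every rejected variant
carries a deterministic primary reason (the first failing filter):

1. **germline** — key present in matched germline DNA;
2. **popfreq** — population allele frequency > 1% (a missing annotation
   counts as 0: absent evidence must not discard a variant);
3. **depth** — positional depth < 300×;
4. **chip** — key in a CHIP database, or seen with ≥ 2 high-quality
   support reads in the matched PBL sample (both routes independently
   switchable);
5. **background** — the error-model test above (SNVs only);
6. **support** — class-specific minimum high-quality support reads:

   | class | flag | threshold |
   |---|---|---|
   | tissue-derived | driver | ≥ 2 |
   | tissue-derived | other | ≥ 4 |
   | ctDNA-private | hotspot | ≥ 4 |
   | ctDNA-private | non-hotspot | ≥ 8 |

   Thresholds are inclusive: a variant exactly at its threshold passes.

`hq_support_reads` is taken as an input column; producing it (base
quality ≥ 30, mapping quality ≥ 30 is the convention the synthetic
generator emulates) is the upstream pipeline's job. Where the input
carries no high-quality count (the VCF dialect), it defaults to
`support_reads`.

A sample is MRD-positive when ≥ 1 variant passes everything. The sample's
`ctdna_level` is the mean VAF of passing variants (configurable to max);
its `composition` records whether passing variants were tissue-derived
only, private only, both, or none.

# Longitudinal logic

* **Landmark** status is taken at 1 month ± 7 days after surgery, i.e.
  the day window [23, 37]. When several samples fall inside, the earliest
  wins (no tie rule is standard; earliest keeps lead-time accounting
  consistent). Patients without an in-window sample are `unsampled` and
  excluded from landmark analyses but retained longitudinally.
* **Longitudinal** status is positive iff any call up to and including
  the recurrence day is positive; samples drawn after recurrence carry no
  surveillance information and are ineligible.
* **Lead time** = (recurrence day − day of *first* positive eligible
  call) / 30.4375, floored at zero. Months are always days/30.4375 so
  reports are reproducible. Whether a confirmed-positive pair should be
  required instead of the first positive sample is an open design point
  in the field; this package uses the first positive sample.
* **DFS** is time from surgery to first radiologic recurrence, censored
  at last follow-up; **OS** time to death, censored likewise.

Clearance trajectories around adjuvant therapy bucket calls into
pre-adjuvant / during / post / endpoint phases (the endpoint is the
recurrence sample for recurrent patients, else the last follow-up
sample); each sampled phase is represented by its latest call. The
decision table, applied in order:

| condition | category |
|---|---|
| no pre-adjuvant sample, or no later sampled phase | `not_evaluable` |
| no phase positive | `never_positive` |
| pre positive; a later negative phase exists and every phase after it is negative | `cleared_durable` |
| pre positive; a later negative phase is followed by a positive one | `cleared_then_regained` |
| otherwise (positivity persists, or emerges without ever clearing) | `persistent_or_rising` |

The last row also covers the case the natural-language description leaves
open — a patient negative before therapy who turns positive later — which
we deliberately classify as `persistent_or_rising`: the signal emerged and
never cleared.

# Cohort statistics

All survival machinery is implemented in the package rather than
delegated, and cross-checked against independent oracles in the tests
(the `survival` package, hand-computed product-limit tables, a
10,000-permutation log-rank null, simulations with known hazard ratios).

* **Contingency**: TP = positive & recurred, etc.; sensitivity
  TP/(TP+FN), specificity TN/(TN+FP), NPV TN/(TN+FN), and per-status
  recurrence rates. Ratios with zero denominators are reported missing,
  never 0. Percentages print half-up to one decimal.
* **Kaplan–Meier**: product-limit with censored-at-t observations kept in
  the risk set at t; S(0) = 1, right-continuous, non-increasing.
* **Log-rank**: k-group O−E statistic with tie-corrected hypergeometric
  variance and the usual (N−1)-denominator convention (so at a single
  event time the statistic is (N−1)/N times the Pearson χ² of the 2×2
  table), referred to χ² with k−1 degrees of freedom.
* **Cox**: Newton–Raphson maximization of the partial likelihood with
  Efron tie handling (the standard modern default; stated because the
  choice affects tied data) and step halving; Wald CIs on the log scale;
  the global score test at β = 0 is returned (for one untied binary
  covariate it equals the log-rank statistic, a relation the tests verify
  to 1e-6). `cox_fit()` codes stage as ordinal 0–3, histology as
  non-adenocarcinoma vs adenocarcinoma, lymph-node involvement and MRD
  statuses as binary; with `selection = "univariate_first"` each
  covariate is screened alone at two-sided p < 0.05 (no multiplicity
  correction — none is standard in this reporting style) before entering
  the multivariate model. Non-convergence raises an error with the
  iteration state; |β| > 15 triggers a separation warning.
* **Group tests**: Mann–Whitney U and the paired Wilcoxon signed-rank
  test use exact enumeration (dynamic programming over rank sums) up to
  n = 25 without ties and a tie- and continuity-corrected normal
  approximation beyond; Fisher's exact 2×2 enumerates the full
  hypergeometric support; Pearson's χ² applies no continuity correction;
  Student's t is the pooled-variance form.

# The synthetic cohort generator

The generator exists so that every other module is testable with known
ground truth; it emulates read-count data, never reads. Its defaults are
the package's reference cohort: 177 patients, stage I/II/III mix
0.503/0.158/0.333, 84.2% adenocarcinoma, mean effective plasma depth
4312× (negative-binomial, dispersion 8), a ~500-sample healthy panel at
~3000×, per-site error rates from Beta(2, 19998) (mean 1e-4), 3–6-monthly
sampling with an 82.5% landmark-sampling rate, and tumor profiles sized
so the cohort median is ~6 variants (range reaching the tens).

Disease dynamics are deliberately simple:

* recurrence is exponential with stage-specific monthly hazards
  0.007/0.018/0.030, under follow-up uniform on 6–30 months — chosen so a
  ~16-month-median-follow-up cohort realizes ≈ 23% recurrence;
* ctDNA shedding is a per-patient stage-dependent Bernoulli
  (0.40/0.65/0.85) — these probabilities are assumptions, set so the
  realized landmark (~25%) and longitudinal (~31%) positivity rates and
  the sensitivity ceiling (shedding given recurrence ≈ 0.7) land in the
  clinically reported range for standardized-panel MRD surveillance of
  this case mix;
* the tumor ctDNA fraction grows exponentially backward from recurrence
  (`growth_per_month` 0.18 from a lognormal fraction at recurrence,
  median 2%) — this knob directly controls simulated lead times (median
  ≈ 4 months at default); a transient post-surgery residual component
  (probability 0.35 among shedders, lognormal median 0.3%, decaying
  0.5/month) produces early positives that clear, i.e. the
  false-positive phenomenology of landmark testing and the
  `cleared_durable` trajectories; adjuvant therapy suppresses shedding
  (×0.05) while it runs, except at recurrence itself;
* ctDNA-private variants are tumor subclones excluded from the tissue
  profile draw; CHIP variants (15% of patients) appear in plasma *and*
  PBL at their clonal fraction; germline variants appear at ~50% VAF in
  both.

All randomness flows from one seed through per-patient substreams, so a
fixed seed yields a byte-identical cohort. Ground truth (per-patient
recurrence/shedding, per-sample true ctDNA fraction, per-variant class
among tumor/germline/chip/error) is written to separate `truth_*.tsv`
files and never into pipeline inputs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment and strand artifacts, trinucleotide
error context, fragmentomics, panel design bias, imaging-schedule
irregularity, non-exponential hazards, and any correlation between
mutation identity and shedding. Results on synthetic cohorts validate the
*machinery*, not clinical performance.

# Numerical and edge-case choices

* Beta-binomial tails are summed directly in log space over the smaller
  tail; at the $\alpha+\beta$ cap of $10^{10}$ the difference from the
  exact binomial tail is below $2\times10^{-7}$ absolute on the tested
  grid.
* The method-of-moments $\hat\rho$ is clamped to $[0, 1)$; non-positive
  moment estimates collapse to the (near-)binomial cap.
* `pct1()`/`pct1_value()` round half-up (floor(x·1000+0.5)/10), matching
  conventional clinical printing; this is applied to *reported*
  percentages only, never inside computations.
* Zero-depth observations have VAF defined as 0; the background test
  refuses them.
* Empty variant tables are legal everywhere (a plasma sample with no
  candidate variants is simply negative).
* In `contingency()`, `unsampled`/missing statuses are excluded before
  counting; an all-excluded input errors rather than fabricating zeros.
* Problem sizes in the test suite (e.g. 200-site recovery panels,
  10,000 background draws, n = 400 hazard-ratio recovery, one
  177-patient end-to-end run) were chosen as the smallest sizes at which
  the corresponding statistical checks are stable multi-sigma assertions.

# Known limitations

* The caller never rescues a sub-threshold tissue-derived variant seen
  repeatedly across time points, although some MRD assays do aggregate
  longitudinal evidence; positivity is strictly per-sample here.
* Structural variants and copy-number evidence contribute nothing to MRD
  calls (tissue-only concepts in this design).
* The background model has no trinucleotide-context smoothing and no
  strand awareness; sites unseen in the healthy panel inherit the pooled
  fallback, which may be conservative or anti-conservative for
  atypical sites.
* OS analyses beyond Kaplan–Meier/log-rank are not provided, and no
  propensity-score matching is implemented.
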