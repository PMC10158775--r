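# ctmrd

Tumor-informed circulating tumor DNA (ctDNA) molecular residual disease
(MRD) calling and postoperative surveillance analytics.

After curative-intent surgery for solid tumors (the package's defaults are
tuned to resectable non-small-cell lung cancer), microscopic residual
disease sheds tumor DNA into plasma at sub-percent allele fractions —
often months before imaging can see a relapse. Detecting it from a
standardized targeted panel requires separating a handful of true mutant
reads from sequencing error, germline variation and clonal hematopoiesis
(CHIP), and then turning serial per-sample calls into clinically
meaningful quantities: landmark and longitudinal MRD status, lead time
over radiologic recurrence, and survival stratification.

`ctmrd` implements that pipeline end to end for variant-level input (it
consumes variant calls with read counts; it does not align reads):

* **Background error model** — for each targeted SNV site, a
  beta-binomial error distribution fitted by the method of moments across
  a healthy-plasma panel (~500 samples at ~3000×), with a pooled
  cross-site fallback for unseen sites. A plasma variant with `s` support
  reads at depth `n` is kept only if the one-sided tail
  `P(X ≥ s | X ~ BetaBin(n, α, β))` falls below the significance level
  (default 0.01).
* **Rule-based MRD caller** — plasma variants are classified
  *tissue-derived* (exact `chrom:pos:ref:alt` key present in the matched
  tumor-tissue profile) or *ctDNA-private* (absent), then pass a fixed,
  logged filter cascade: germline → population frequency (>1% excluded) →
  positional depth (<300× excluded) → CHIP (database key or ≥2
  high-quality reads in matched peripheral-blood-leukocyte DNA) →
  background test → class-specific support thresholds
  (tissue-derived driver ≥2 HQ reads, tissue-derived other ≥4, private
  hotspot ≥4, private non-hotspot ≥8). A sample is MRD-positive when at
  least one variant survives.
* **Longitudinal engine** — landmark status (1 month ± 7 days after
  surgery), longitudinal status over all samples up to and including
  recurrence, lead time from first positivity to radiologic recurrence,
  and ctDNA clearance trajectories around adjuvant therapy.
* **Cohort statistics, from first principles** — sensitivity/specificity/
  NPV contingency metrics, Kaplan–Meier product-limit curves, the
  k-group log-rank test, Cox proportional hazards (Newton–Raphson, Efron
  ties, univariate screening at p < 0.05 before the multivariate model),
  Mann–Whitney U, Student's t, Pearson χ², exact Fisher and the paired
  Wilcoxon signed-rank test. The `survival` package and base-R tests are
  used only as independent oracles in the test suite.
* **Synthetic cohort generator** — fully synthetic patients (stage mix,
  recurrence hazards, ctDNA shedding and growth, CHIP, germline, per-site
  error, a healthy panel, 3–6-monthly sampling) with ground-truth labels,
  so the entire pipeline is testable without patient data.

## Worked example

```r
library(ctmrd)

# simulate a small surveillance cohort with known ground truth
sim <- simulate_cohort(sim_config(n_patients = 40), seed = 7)
#> sim_cohort: 40 patients (12 recurred), 153 plasma samples,
#>             250 panel sites, 500 healthy samples

# fit the per-site error background from the healthy-plasma panel
bg <- build_background(sim$healthy)
#> background_model: 250 sites from 500 healthy samples (fallback rate 0.000101)

# write the cohort in pipeline formats, read it back, call every sample
dir <- tempfile()
write_cohort(sim, dir)
cohort <- read_cohort(file.path(dir, "manifest.tsv"),
                      file.path(dir, "clinical.tsv"))
calls <- call_cohort(cohort, bg)
calls[[2]]
#> mrd_call P001/P001_T02 (day 340): POSITIVE, 6 passing variant(s), level 0.005553

# landmark / longitudinal status, lead times, cohort statistics
records <- build_patient_records(cohort, calls)
tab <- patient_table(records)
contingency(tab, "longitudinal_status")
#> contingency (n=40): tp=9 fp=7 fn=3 tn=21
#>   sensitivity 75.0%, specificity 75.0%, ppv 56.3%, npv 87.5%
median(tab$lead_time_months, na.rm = TRUE)
#> [1] 4.468172

keep <- tab$longitudinal_status %in% c("positive", "negative")
survfit_groups(tab$dfs_days[keep], tab$dfs_event[keep],
               tab$longitudinal_status[keep])
#> survival_fit: 2 group(s); log-rank chi2=11.673 (df=1), p=0.0006341
```

Reading those numbers: of the 12 patients who relapsed, 9 were
ctDNA-positive at some eligible time point (sensitivity 75.0%); the 7
"false" positives are dominated by transiently shedding patients whose
residual disease cleared. Positive patients recur markedly faster
(log-rank p ≈ 6e-4), and the median interval from first ctDNA positivity
to radiologic recurrence is ~4.5 months in this draw.

A thin command-line front end over the same functions ships in
`inst/cli/ctmrd` (`background`, `call`, `cohort`, `simulate`
subcommands).

## Input formats

Variant tables are TSV (required columns `chrom, pos, ref, alt,
total_depth, support_reads, hq_support_reads`; optional `pop_af,
is_hotspot, is_driver, gene`) or a single-sample VCF subset
(`AD`/`DP` plus INFO keys `POPAF`, `HOTSPOT`, `DRIVER`). Cohorts are
described by a sample manifest and a clinical table (see
`?read_manifest`, `?read_clinical`). Coordinates are 1-based, VCF
convention; plasma/tissue matching is by exact key, so both inputs must
share one indel normalization.

See the methods vignette (`vignettes/ctdna-mrd-methods.Rmd`) for the
model details, parameter choices and limitations.
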