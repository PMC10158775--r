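Package: ctmrd
Title: Tumor-Informed ctDNA Minimal Residual Disease Calling and Surveillance Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for postoperative circulating tumor DNA (ctDNA)
    molecular residual disease (MRD) analysis from targeted-panel variant calls.
    Builds a per-site sequencing-error background from a healthy-plasma panel
    (beta-binomial, method-of-moments), classifies plasma variants as
    tissue-derived or ctDNA-private against a matched tumor profile, applies
    class-specific high-quality support-read thresholds and
    germline/population-frequency/depth/clonal-hematopoiesis filters, and
    derives per-sample MRD positivity. Turns serial calls plus clinical
    timelines into landmark status, longitudinal status, lead time and
    adjuvant-therapy clearance trajectories, and computes cohort-level
    contingency metrics, Kaplan-Meier/log-rank/Cox survival analyses and
    nonparametric group comparisons from first principles. Includes a
    synthetic-cohort generator with known ground truth so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    vcfR,
    jsonlite
Config/testthat/edition: 3
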