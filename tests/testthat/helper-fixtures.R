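# Shared builders and independent oracles for the test suite.

# quick variant-row builder; vaf derived from counts
make_obs <- function(chrom = "chr7", pos = 55249071, ref = "C", alt = "T",
                     total_depth = 3000L, support_reads = 10L,
                     hq_support_reads = support_reads, pop_af = 0,
                     is_hotspot = FALSE, is_driver = FALSE, gene = "EGFR") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             total_depth = as.integer(total_depth),
             support_reads = as.integer(support_reads),
             hq_support_reads = as.integer(hq_support_reads),
             vaf = ifelse(total_depth > 0, support_reads / total_depth, 0),
             pop_af = pop_af, is_hotspot = is_hotspot,
             is_driver = is_driver, gene = gene,
             stringsAsFactors = FALSE)
}

# mrd_call stub for longitudinal tests (no variant detail needed)
make_call <- function(day, positive, level = if (positive) 0.01 else 0,
                      patient_id = "P001",
                      composition = if (positive) "tissue_only" else "none") {
  structure(list(patient_id = patient_id,
                 sample_id = sprintf("%s_d%d", patient_id, day),
                 days_from_surgery = day, positive = positive,
                 n_passing = as.integer(positive),
                 ctdna_level = level, composition = composition,
                 variants = NULL),
            class = "mrd_call")
}

make_clinical_row <- function(patient_id = "P001", stage = "II",
                              histology = "adenocarcinoma",
                              recurrence_day = NA_real_,
                              death_day = NA_real_,
                              last_followup_day = 720,
                              adjuvant = "none",
                              adjuvant_start_day = NA_real_,
                              adjuvant_end_day = NA_real_,
                              lymph_node_involved = FALSE) {
  data.frame(patient_id = patient_id, stage = stage, histology = histology,
             surgery_day = 0L, recurrence_day = recurrence_day,
             death_day = death_day, last_followup_day = last_followup_day,
             adjuvant = adjuvant, adjuvant_start_day = adjuvant_start_day,
             adjuvant_end_day = adjuvant_end_day,
             lymph_node_involved = lymph_node_involved,
             smoking = "never", stringsAsFactors = FALSE)
}

# Independent brute-force rule evaluator for the caller cascade, coded
# directly from the published filtering rules as literal if-else logic.
# Returns list(passing, reason) for a single observation.
brute_force_rule <- function(in_tissue, is_driver, is_hotspot, hq_support,
                             total_depth, pop_af, in_germline = FALSE,
                             in_chip = FALSE, pbl_hq = 0,
                             background_significant = TRUE) {
  if (in_germline) return(list(passing = FALSE, reason = "germline"))
  if (pop_af > 0.01) return(list(passing = FALSE, reason = "popfreq"))
  if (total_depth < 300) return(list(passing = FALSE, reason = "depth"))
  if (in_chip || pbl_hq >= 2) return(list(passing = FALSE, reason = "chip"))
  if (!background_significant) {
    return(list(passing = FALSE, reason = "background"))
  }
  need <- if (in_tissue) {
    if (is_driver) 2 else 4
  } else {
    if (is_hotspot) 4 else 8
  }
  if (hq_support >= need) list(passing = TRUE, reason = ".")
  else list(passing = FALSE, reason = "support")
}

# small simulated cohort processed through the full pipeline
run_small_pipeline <- function(seed = 42, n_patients = 25,
                               n_panel_sites = 60, n_healthy = 60, ...) {
  cfg <- sim_config(n_patients = n_patients, n_panel_sites = n_panel_sites,
                    n_healthy = n_healthy, ...)
  sim <- simulate_cohort(cfg, seed = seed)
  bg <- build_background(sim$healthy)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_cohort(sim, dir)
  cohort <- read_cohort(file.path(dir, "manifest.tsv"),
                        file.path(dir, "clinical.tsv"))
  calls <- call_cohort(cohort, bg)
  records <- build_patient_records(cohort, calls)
  list(sim = sim, bg = bg, dir = dir, cohort = cohort, calls = calls,
       records = records, tab = patient_table(records))
}
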