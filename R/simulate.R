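# Synthetic-cohort generator with known ground truth.
#
# Emulates a resectable-lung-cancer MRD surveillance cohort: a targeted
# panel of SNV sites, stage-dependent recurrence and ctDNA shedding,
# sub-percent plasma VAFs that grow exponentially toward recurrence,
# per-site sequencing error, CHIP variants shared between plasma and PBL,
# germline contamination, a healthy-plasma background panel, and 3-6
# monthly sampling with a 1-month landmark visit. Counts only: no reads,
# no alignment artifacts.

#' Simulation configuration
#'
#' Defaults reproduce the published cohort's headline structure: 177
#' patients; stage mix I/II/III = 0.503/0.158/0.333; 84.2% adenocarcinoma;
#' mean effective plasma depth 4312x; ~23% recurrence under a ~16-month
#' median follow-up (stage-specific exponential hazards 0.007/0.018/0.030
#' per month); 82.5% of patients with a landmark sample in the 1-month
#' (+/-7 day) window; tumor profiles sized so the cohort median is ~6
#' variants; a ~500-sample healthy panel at ~3000x with per-site error
#' rates drawn from Beta(2, 19998) (mean 1e-4).
#'
#' @param n_patients Cohort size.
#' @param stage_probs Probabilities over stages I/II/III.
#' @param adeno_prob Adenocarcinoma probability.
#' @param recurrence_hazard Monthly exponential recurrence hazard per stage.
#' @param shedding_prob Per-stage probability that the tumor sheds ctDNA.
#' @param mean_depth,depth_dispersion Negative-binomial plasma depth model.
#' @param error_alpha0,error_beta0 Beta prior from which per-site error
#'   rates are drawn (`error_alpha0 = 0` gives error-free sequencing).
#' @param vaf_detect_meanlog,vaf_detect_sdlog Lognormal tumor ctDNA
#'   fraction at recurrence.
#' @param growth_per_month Exponential ctDNA growth rate toward recurrence
#'   (controls simulated lead times).
#' @param resid_prob Probability that a shedding patient carries transient
#'   post-surgery residual ctDNA (micro-residual disease that clears
#'   without recurrence).
#' @param resid_meanlog,resid_sdlog,resid_decay Post-surgery residual ctDNA
#'   fraction (lognormal at day 0, exponential monthly decay) for patients
#'   with residual shedding.
#' @param chip_prob Per-patient probability of carrying CHIP variants.
#' @param germline_mean Poisson mean of germline variants observable per
#'   patient on the panel (0 disables germline emission).
#' @param sampling_interval_months Range of months between serial samples.
#' @param followup_min_months,followup_max_months Uniform follow-up window.
#' @param landmark_prob Probability a patient has an in-window landmark
#'   sample.
#' @param tissue_nb_size,tissue_nb_mu Negative-binomial (plus 1) tumor
#'   mutation burden.
#' @param private_rate Poisson mean of ctDNA-private subclonal variants
#'   (tumor variants absent from the tissue profile draw).
#' @param n_panel_sites Targeted panel size (SNV sites).
#' @param n_healthy,healthy_depth Healthy panel size and mean depth.
#' @param pbl_depth Mean PBL depth.
#' @param hq_frac Probability a support read is high-quality.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 177,
                       stage_probs = c(I = 0.503, II = 0.158, III = 0.333),
                       adeno_prob = 0.842,
                       recurrence_hazard = c(I = 0.007, II = 0.018,
                                             III = 0.030),
                       shedding_prob = c(I = 0.40, II = 0.65, III = 0.85),
                       mean_depth = 4312, depth_dispersion = 8,
                       error_alpha0 = 2, error_beta0 = 19998,
                       vaf_detect_meanlog = log(0.02),
                       vaf_detect_sdlog = 0.8,
                       growth_per_month = 0.18,
                       resid_prob = 0.35,
                       resid_meanlog = log(0.003), resid_sdlog = 1,
                       resid_decay = 0.5,
                       chip_prob = 0.15,
                       germline_mean = 3,
                       sampling_interval_months = c(3, 6),
                       followup_min_months = 6, followup_max_months = 30,
                       landmark_prob = 0.825,
                       tissue_nb_size = 1.7, tissue_nb_mu = 5.3,
                       private_rate = 0.7,
                       n_panel_sites = 250,
                       n_healthy = 500, healthy_depth = 3000,
                       pbl_depth = 1000, hq_frac = 0.92) {
  cfg <- as.list(environment())
  probs <- c(cfg$stage_probs, cfg$adeno_prob, cfg$shedding_prob,
             cfg$chip_prob, cfg$landmark_prob, cfg$hq_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$stage_probs) - 1) > 0.02) {
    stop("stage_probs must sum to ~1", call. = FALSE)
  }
  cfg$stage_probs <- cfg$stage_probs / sum(cfg$stage_probs)
  if (any(cfg$recurrence_hazard <= 0)) {
    stop("recurrence hazards must be positive", call. = FALSE)
  }
  if (cfg$n_patients < 1 || cfg$n_panel_sites < 2 || cfg$n_healthy < 2) {
    stop("n_patients, n_panel_sites and n_healthy must be positive",
         call. = FALSE)
  }
  if (cfg$mean_depth <= 0 || cfg$healthy_depth <= 0) {
    stop("depths must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.PANEL_GENES <- c("EGFR", "TP53", "KRAS", "LRP1B", "RBM10", "PIK3CA",
                  "SMARCA4", "STK11", "ALK", "BRAF", "MET", "ERBB2",
                  "KEAP1", "NF1", "RB1", "CDKN2A", "ATM", "CTNNB1",
                  "FGFR1", "NTRK1")
.DRIVER_GENES <- c("EGFR", "KRAS", "PIK3CA", "ALK", "BRAF", "MET",
                   "ERBB2", "NTRK1")

# Deterministic synthetic panel; hotspot and driver-position flags and a
# few common-polymorphism sites (pop_af up to 5%) are drawn from the
# supplied RNG state.
.make_panel <- function(cfg) {
  n <- cfg$n_panel_sites
  gene <- rep(.PANEL_GENES, length.out = n)
  chrom <- paste0("chr", (match(gene, .PANEL_GENES) %% 21) + 1)
  pos <- 1000000L + seq_len(n) * 997L
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(n) %% 4) + 1L]
  alt <- bases[((seq_len(n) + 1L) %% 4) + 1L]
  is_driver_gene <- gene %in% .DRIVER_GENES
  is_hotspot <- stats::runif(n) < ifelse(is_driver_gene, 0.25, 0.03)
  is_driver <- is_driver_gene & (is_hotspot | stats::runif(n) < 0.3)
  pop_af <- ifelse(stats::runif(n) < 0.05, stats::runif(n, 0, 0.05), 0)
  err_rate <- if (cfg$error_alpha0 == 0) numeric(n) else
    stats::rbeta(n, cfg$error_alpha0, cfg$error_beta0)
  data.frame(site_id = seq_len(n), chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, is_hotspot = is_hotspot,
             is_driver = is_driver, pop_af = pop_af, err_rate = err_rate,
             stringsAsFactors = FALSE)
}

.rdepth <- function(n, mu, size) {
  pmax(stats::rnbinom(n, mu = mu, size = size), 1L)
}

# variant rows for one sample given per-site signal fractions
.emit_sample <- function(panel, signal, mean_depth, size, hq_frac) {
  depth <- .rdepth(nrow(panel), mean_depth, size)
  p <- pmin(signal + panel$err_rate, 0.999)
  support <- stats::rbinom(nrow(panel), depth, p)
  keep <- support >= 1L
  hq <- stats::rbinom(sum(keep), support[keep], hq_frac)
  df <- data.frame(
    chrom = panel$chrom[keep], pos = panel$pos[keep],
    ref = panel$ref[keep], alt = panel$alt[keep],
    total_depth = depth[keep], support_reads = support[keep],
    hq_support_reads = hq,
    vaf = support[keep] / depth[keep],
    pop_af = panel$pop_af[keep], is_hotspot = panel$is_hotspot[keep],
    is_driver = panel$is_driver[keep], gene = panel$gene[keep],
    stringsAsFactors = FALSE)
  list(variants = df, site_id = panel$site_id[keep])
}

#' Simulate one patient
#'
#' @param cfg A [sim_config()].
#' @param panel Panel table from the cohort simulation.
#' @param patient_id Identifier string.
#' @return List: `clinical` (one-row clinical table), `samples` (plasma
#'   sample list with variant tables), `tissue`, `pbl` (variant tables),
#'   `truth` (per-patient, per-sample and per-variant ground truth).
#' @keywords internal
simulate_patient <- function(cfg, panel, patient_id) {
  stage <- sample(names(cfg$stage_probs), 1L, prob = cfg$stage_probs)
  histology <- if (stats::runif(1) < cfg$adeno_prob) "adenocarcinoma" else
    sample(c("squamous", "adenosquamous", "other"), 1L,
           prob = c(0.7, 0.15, 0.15))
  lymph <- stats::runif(1) < c(I = 0.1, II = 0.5, III = 0.8)[[stage]]
  followup_m <- stats::runif(1, cfg$followup_min_months,
                             cfg$followup_max_months)
  fup_day <- round(followup_m * 30.4375)
  t_rec_m <- stats::rexp(1, cfg$recurrence_hazard[[stage]])
  recurred <- t_rec_m < followup_m
  rec_day <- if (recurred) max(round(t_rec_m * 30.4375), 30L) else NA_real_
  death_day <- NA_real_
  if (recurred && stats::runif(1) < 0.17) {
    death_day <- min(rec_day + round(stats::rexp(1, 1 / 6) * 30.4375),
                     fup_day)
  }
  adj_probs <- switch(stage,
    I = c(none = 0.80, chemo = 0.08, targeted = 0.10, chemo_immuno = 0.02),
    II = c(none = 0.30, chemo = 0.40, targeted = 0.25, chemo_immuno = 0.05),
    III = c(none = 0.15, chemo = 0.40, targeted = 0.35, chemo_immuno = 0.10))
  adjuvant <- sample(names(adj_probs), 1L, prob = adj_probs)
  adj_start <- if (adjuvant == "none") NA_real_ else
    round(stats::runif(1, 30, 50))
  adj_end <- if (adjuvant == "none") NA_real_ else adj_start + 120

  # tumor variant set: tissue-profiled clones plus private subclones,
  # drawn from panel sites that are not common polymorphisms
  eligible <- panel[panel$pop_af <= 0.01, , drop = FALSE]
  n_tissue <- 1L + stats::rnbinom(1L, size = cfg$tissue_nb_size,
                                  mu = cfg$tissue_nb_mu)
  n_tissue <- min(n_tissue, nrow(eligible) - 4L)
  n_private <- stats::rpois(1L, cfg$private_rate)
  picked <- sample(nrow(eligible), n_tissue + n_private)
  tissue_sites <- eligible$site_id[picked[seq_len(n_tissue)]]
  private_sites <- eligible$site_id[
    picked[seq_len(n_private) + n_tissue]]
  shedding <- stats::runif(1) < cfg$shedding_prob[[stage]]

  # germline and CHIP sites among the remaining panel
  rest <- setdiff(panel$site_id, c(tissue_sites, private_sites))
  n_germ <- stats::rpois(1L, cfg$germline_mean)
  germ_sites <- sample(rest, min(n_germ, length(rest)))
  rest <- setdiff(rest, germ_sites)
  has_chip <- stats::runif(1) < cfg$chip_prob
  chip_sites <- if (has_chip) sample(rest, sample(1:2, 1L)) else integer()
  chip_vaf <- stats::setNames(exp(stats::runif(length(chip_sites),
                                               log(0.004), log(0.05))),
                              chip_sites)

  # tissue variant table (tissue-profile sites only; high tumor-content VAF)
  tpanel <- panel[panel$site_id %in% tissue_sites, , drop = FALSE]
  t_depth <- .rdepth(nrow(tpanel), 800, 10)
  t_vaf <- stats::runif(nrow(tpanel), 0.05, 0.5)
  t_support <- pmax(stats::rbinom(nrow(tpanel), t_depth, t_vaf), 1L)
  tissue_tab <- data.frame(
    chrom = tpanel$chrom, pos = tpanel$pos, ref = tpanel$ref,
    alt = tpanel$alt, total_depth = t_depth, support_reads = t_support,
    hq_support_reads = stats::rbinom(nrow(tpanel), t_support, cfg$hq_frac),
    vaf = t_support / t_depth, pop_af = tpanel$pop_af,
    is_hotspot = tpanel$is_hotspot, is_driver = tpanel$is_driver,
    gene = tpanel$gene, stringsAsFactors = FALSE)

  # PBL: germline at ~50% VAF plus CHIP at its clonal fraction
  pbl_sites <- c(germ_sites, as.integer(names(chip_vaf)))
  ppanel <- panel[match(pbl_sites, panel$site_id), , drop = FALSE]
  p_depth <- .rdepth(nrow(ppanel), cfg$pbl_depth, 10)
  p_vaf <- c(stats::runif(length(germ_sites), 0.4, 0.6),
             unname(chip_vaf))
  p_support <- pmax(stats::rbinom(nrow(ppanel), p_depth, p_vaf), 1L)
  pbl_tab <- data.frame(
    chrom = ppanel$chrom, pos = ppanel$pos, ref = ppanel$ref,
    alt = ppanel$alt, total_depth = p_depth, support_reads = p_support,
    hq_support_reads = pmax(stats::rbinom(nrow(ppanel), p_support,
                                          cfg$hq_frac), 1L),
    vaf = p_support / p_depth, pop_af = ppanel$pop_af,
    is_hotspot = ppanel$is_hotspot, is_driver = ppanel$is_driver,
    gene = ppanel$gene, stringsAsFactors = FALSE)

  # sampling schedule
  days <- numeric()
  if (stats::runif(1) < cfg$landmark_prob) {
    days <- round(stats::runif(1, 24, 36))
  }
  end_day <- if (recurred) rec_day else fup_day
  t <- if (length(days)) days[1] else 0
  repeat {
    t <- t + round(stats::runif(1, cfg$sampling_interval_months[1],
                                cfg$sampling_interval_months[2]) * 30.4375)
    if (t > end_day) break
    days <- c(days, t)
  }
  if (recurred) days <- sort(unique(c(days[days <= rec_day], rec_day)))
  if (length(days) == 0L) days <- min(45, end_day)

  # per-sample tumor ctDNA fraction
  f_rec <- exp(stats::rnorm(1, cfg$vaf_detect_meanlog, cfg$vaf_detect_sdlog))
  has_resid <- stats::runif(1) < cfg$resid_prob
  resid0 <- if (has_resid)
    exp(stats::rnorm(1, cfg$resid_meanlog, cfg$resid_sdlog)) else 0
  frac_at <- function(day) {
    if (!shedding) return(0)
    m <- day / 30.4375
    f <- resid0 * exp(-cfg$resid_decay * m)
    if (recurred) {
      f <- f + f_rec * exp(-cfg$growth_per_month * (rec_day - day) / 30.4375)
    }
    min(f, 0.4)
  }
  # therapy suppresses shedding while it runs (clearance trajectories);
  # a recurrence during therapy has escaped suppression by definition
  suppress <- function(day) {
    if (is.na(adj_start)) return(1)
    if (recurred && day >= rec_day - 15) return(1)
    if (day >= adj_start && day <= adj_end + 30) 0.05 else 1
  }

  tumor_sites <- c(tissue_sites, private_sites)
  w <- stats::runif(length(tumor_sites), 0.3, 1)  # clonal weights
  samples <- list()
  truth_samples <- list()
  truth_variants <- list()
  for (i in seq_along(days)) {
    day <- days[i]
    f <- frac_at(day) * suppress(day)
    signal <- numeric(nrow(panel))
    if (f > 0 && length(tumor_sites)) {
      signal[match(tumor_sites, panel$site_id)] <- pmin(f * w, 0.45)
    }
    if (length(germ_sites)) {
      signal[match(germ_sites, panel$site_id)] <-
        stats::runif(length(germ_sites), 0.4, 0.6)
    }
    if (length(chip_sites)) {
      signal[match(chip_sites, panel$site_id)] <- unname(chip_vaf)
    }
    em <- .emit_sample(panel, signal, cfg$mean_depth,
                       cfg$depth_dispersion, cfg$hq_frac)
    sid <- sprintf("%s_T%02d", patient_id, i)
    samples[[i]] <- list(sample_id = sid, days_from_surgery = day,
                         variants = em$variants)
    truth_samples[[i]] <- data.frame(
      patient_id = patient_id, sample_id = sid, days_from_surgery = day,
      true_ctdna_fraction = f, stringsAsFactors = FALSE)
    cls <- ifelse(em$site_id %in% tumor_sites & f > 0, "tumor",
                  ifelse(em$site_id %in% germ_sites, "germline",
                         ifelse(em$site_id %in% chip_sites, "chip",
                                "error")))
    truth_variants[[i]] <- data.frame(
      sample_id = rep(sid, nrow(em$variants)),
      key = variant_key(em$variants),
      true_class = cls, stringsAsFactors = FALSE)
  }

  clinical <- data.frame(
    patient_id = patient_id, stage = stage, histology = histology,
    surgery_day = 0L,
    recurrence_day = rec_day, death_day = death_day,
    last_followup_day = fup_day, adjuvant = adjuvant,
    adjuvant_start_day = adj_start, adjuvant_end_day = adj_end,
    lymph_node_involved = lymph,
    smoking = sample(c("never", "former", "current"), 1L,
                     prob = c(0.6, 0.25, 0.15)),
    stringsAsFactors = FALSE)
  truth_patient <- data.frame(
    patient_id = patient_id, stage = stage, shedding = shedding,
    recurred = recurred, recurrence_day = rec_day,
    n_tissue_variants = n_tissue, n_private_variants = n_private,
    stringsAsFactors = FALSE)
  list(clinical = clinical, samples = samples, tissue = tissue_tab,
       pbl = pbl_tab,
       truth = list(patient = truth_patient,
                    samples = do.call(rbind, truth_samples),
                    variants = do.call(rbind, truth_variants)))
}

#' Simulate a healthy-plasma background panel
#'
#' @param cfg A [sim_config()].
#' @param panel Panel table (uses its per-site error rates).
#' @return `data.frame` of per-sample, per-site observations in the format
#'   [build_background()] consumes (all covered sites emitted, including
#'   zero-support ones).
#' @export
simulate_healthy_panel <- function(cfg, panel) {
  n_sites <- nrow(panel)
  do.call(rbind, lapply(seq_len(cfg$n_healthy), function(i) {
    depth <- .rdepth(n_sites, cfg$healthy_depth, cfg$depth_dispersion)
    support <- stats::rbinom(n_sites, depth, panel$err_rate)
    data.frame(sample_id = sprintf("H%04d", i),
               chrom = panel$chrom, pos = panel$pos, ref = panel$ref,
               alt = panel$alt, total_depth = depth,
               support_reads = support, stringsAsFactors = FALSE)
  }))
}

#' Simulate a full cohort in memory
#'
#' All randomness flows from `seed` through one master generator that
#' derives a named substream per patient, so a fixed seed yields a
#' byte-identical cohort.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Object of class `sim_cohort`: `panel`, `clinical`, `patients`
#'   (per-patient samples/tissue/pbl), `healthy`, `truth` (patient, sample
#'   and variant tables), `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  panel <- .make_panel(cfg)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_patients)
  healthy_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seeds[i])
    patients[[i]] <- simulate_patient(cfg, panel, sprintf("P%03d", i))
  }
  set.seed(healthy_seed)
  healthy <- simulate_healthy_panel(cfg, panel)
  clinical <- do.call(rbind, lapply(patients, `[[`, "clinical"))
  truth <- list(
    patients = do.call(rbind, lapply(patients, function(p) p$truth$patient)),
    samples = do.call(rbind, lapply(patients, function(p) p$truth$samples)),
    variants = do.call(rbind, lapply(patients, function(p) p$truth$variants)))
  structure(list(panel = panel, clinical = clinical, patients = patients,
                 healthy = healthy, truth = truth, config = cfg,
                 seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d patients (%d recurred), %d plasma samples, %d panel sites, %d healthy samples\n",
    nrow(x$clinical), sum(x$truth$patients$recurred),
    nrow(x$truth$samples), nrow(x$panel),
    length(unique(x$healthy$sample_id))))
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Writes `manifest.tsv`, `clinical.tsv`, per-sample variant TSVs under
#' `variants/`, the healthy panel observations (`healthy_panel.tsv`),
#' ground-truth tables (`truth_patients.tsv`, `truth_samples.tsv`,
#' `truth_variants.tsv` — separate files, never mixed into sample data)
#' and `summary.txt` with realized cohort statistics.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "variants"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list()
  for (p in sim$patients) {
    pid <- p$clinical$patient_id
    for (s in p$samples) {
      f <- file.path("variants", paste0(s$sample_id, ".tsv"))
      write_variant_table(s$variants, file.path(dir, f))
      manifest[[length(manifest) + 1L]] <- data.frame(
        patient_id = pid, sample_id = s$sample_id, material = "plasma",
        days_from_surgery = s$days_from_surgery, variant_file = f,
        stringsAsFactors = FALSE)
    }
    for (mat in c("tissue", "pbl")) {
      tab <- p[[mat]]
      if (is.null(tab) || nrow(tab) == 0L) next
      sid <- sprintf("%s_%s", pid, toupper(mat))
      f <- file.path("variants", paste0(sid, ".tsv"))
      write_variant_table(tab, file.path(dir, f))
      manifest[[length(manifest) + 1L]] <- data.frame(
        patient_id = pid, sample_id = sid, material = mat,
        days_from_surgery = 0, variant_file = f, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$healthy, file.path(dir, "healthy_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$patients, file.path(dir, "truth_patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$variants, file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- mean(sim$truth$patients$recurred)
  med_burden <- stats::median(sim$truth$patients$n_tissue_variants +
                                sim$truth$patients$n_private_variants)
  writeLines(c(
    sprintf("patients: %d", nrow(sim$clinical)),
    sprintf("plasma samples: %d", nrow(sim$truth$samples)),
    sprintf("recurrence rate: %s", pct1(rec)),
    sprintf("median tumor mutation burden: %g", med_burden),
    sprintf("stage counts: %s",
            paste(names(table(sim$clinical$stage)),
                  table(sim$clinical$stage), sep = "=", collapse = " ")),
    sprintf("seed: %d", sim$seed)
  ), file.path(dir, "summary.txt"))
  invisible(dir)
}
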