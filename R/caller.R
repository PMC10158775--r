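# Rule-based MRD caller: tumor-informed classification plus a fixed,
# logged filter cascade.
#
# Filter order is fixed so every rejected variant has a deterministic
# primary reason: germline -> population-frequency -> depth -> CHIP ->
# background test -> support thresholds.

.FILTER_ORDER <- c("germline", "popfreq", "depth", "chip", "background",
                   "support")

#' Default caller configuration
#'
#' @param alpha_level Background-test significance level (default 0.01).
#' @param min_depth Minimum positional depth (default 300, i.e. variants at
#'   < 300x are rejected).
#' @param max_pop_af Maximum population allele frequency (default 0.01;
#'   variants above 1% in ExAC/1000G-style annotation are rejected).
#' @param pbl_min_hq Minimum high-quality support reads in matched PBL for a
#'   plasma variant to be treated as clonal hematopoiesis (default 2).
#' @param thresholds Named integer vector of class-specific minimum
#'   high-quality support reads: tissue-derived driver 2, tissue-derived
#'   other 4, ctDNA-private hotspot 4, ctDNA-private non-hotspot 8.
#' @param background_test Apply the healthy-panel background test to SNVs
#'   (default TRUE; indels always bypass it, the panel models SNVs only).
#' @param use_chip_db Filter on the CHIP key database (default TRUE).
#' @param use_pbl_filter Filter on matched-PBL evidence (default TRUE).
#' @param level_stat How a sample's ctDNA level summarizes passing-variant
#'   VAFs: `"mean"` (default) or `"max"`.
#' @return Named list of caller settings.
#' @export
caller_config <- function(alpha_level = 0.01, min_depth = 300,
                          max_pop_af = 0.01, pbl_min_hq = 2,
                          thresholds = c(tissue_driver = 2L,
                                         tissue_other = 4L,
                                         private_hotspot = 4L,
                                         private_other = 8L),
                          background_test = TRUE, use_chip_db = TRUE,
                          use_pbl_filter = TRUE,
                          level_stat = c("mean", "max")) {
  stopifnot(alpha_level > 0, alpha_level < 1, min_depth >= 1)
  req <- c("tissue_driver", "tissue_other", "private_hotspot",
           "private_other")
  if (!all(req %in% names(thresholds))) {
    stop("thresholds must name tissue_driver, tissue_other, private_hotspot, private_other",
         call. = FALSE)
  }
  list(alpha_level = alpha_level, min_depth = min_depth,
       max_pop_af = max_pop_af, pbl_min_hq = pbl_min_hq,
       thresholds = thresholds, background_test = background_test,
       use_chip_db = use_chip_db, use_pbl_filter = use_pbl_filter,
       level_stat = match.arg(level_stat))
}

#' Build a tissue profile from a tumor-tissue variant table
#'
#' @param patient_id Patient the tissue belongs to.
#' @param tissue_variants Tissue variant table (may be NULL/empty for a
#'   patient without informative tissue).
#' @return Object of class `tissue_profile`: patient_id plus a keyed
#'   `data.frame` of tissue variants with their driver/hotspot flags.
#' @export
tissue_profile <- function(patient_id, tissue_variants = NULL) {
  if (is.null(tissue_variants) || nrow(tissue_variants) == 0L) {
    keys <- data.frame(key = character(), is_driver = logical(),
                       is_hotspot = logical(), stringsAsFactors = FALSE)
  } else {
    keys <- data.frame(key = variant_key(tissue_variants),
                       is_driver = tissue_variants$is_driver,
                       is_hotspot = tissue_variants$is_hotspot,
                       stringsAsFactors = FALSE)
    keys <- keys[!duplicated(keys$key), , drop = FALSE]
  }
  structure(list(patient_id = patient_id, keys = keys),
            class = "tissue_profile")
}

#' Classify plasma variants as tissue-derived or ctDNA-private
#'
#' A plasma variant whose exact (chrom, pos, ref, alt) key occurs in the
#' patient's matched tumor-tissue profile is tissue-derived; otherwise it is
#' ctDNA-private. Driver/hotspot flags recorded on the tissue side are
#' OR-ed onto matched plasma observations.
#'
#' @param obs Plasma variant table.
#' @param profile A [tissue_profile()] for the same patient.
#' @param patient_id Patient owning the plasma sample; must equal the
#'   profile's patient.
#' @return `obs` with columns `variant_class` (`"tissue_derived"` /
#'   `"ctdna_private"`) and updated `is_driver`/`is_hotspot`.
#' @export
classify_variant <- function(obs, profile, patient_id = profile$patient_id) {
  if (!identical(patient_id, profile$patient_id)) {
    stop(sprintf("tissue profile belongs to %s, not %s",
                 profile$patient_id, patient_id), call. = FALSE)
  }
  idx <- match(variant_key(obs), profile$keys$key)
  obs$variant_class <- ifelse(is.na(idx), "ctdna_private", "tissue_derived")
  matched <- !is.na(idx)
  if (any(matched)) {
    obs$is_driver[matched] <- obs$is_driver[matched] |
      profile$keys$is_driver[idx[matched]]
    obs$is_hotspot[matched] <- obs$is_hotspot[matched] |
      profile$keys$is_hotspot[idx[matched]]
  }
  obs
}

#' Apply the pre-classification filters
#'
#' Ordered verdicts per variant: `germline` (key present in matched germline
#' DNA), `popfreq` (population allele frequency > 1%), `depth` (positional
#' depth < `min_depth`), `chip` (key in the CHIP database, or seen in the
#' matched PBL sample with at least `pbl_min_hq` high-quality support
#' reads).
#'
#' @param obs Plasma variant table.
#' @param germline_keys Character vector of germline variant keys.
#' @param chip_keys Character vector of CHIP-database keys.
#' @param pbl_obs Matched-PBL variant table (or NULL).
#' @param config A [caller_config()].
#' @return Logical `data.frame` with columns `germline`, `popfreq`, `depth`,
#'   `chip`; TRUE means the variant PASSES that filter.
#' @export
apply_prefilters <- function(obs, germline_keys = character(),
                             chip_keys = character(), pbl_obs = NULL,
                             config = caller_config()) {
  keys <- variant_key(obs)
  pbl_hit <- rep(FALSE, nrow(obs))
  if (config$use_pbl_filter && !is.null(pbl_obs) && nrow(pbl_obs) > 0L) {
    pk <- variant_key(pbl_obs)
    idx <- match(keys, pk)
    pbl_hit <- !is.na(idx) &
      pbl_obs$hq_support_reads[ifelse(is.na(idx), 1L, idx)] >= config$pbl_min_hq
  }
  chip_db_hit <- if (config$use_chip_db) keys %in% chip_keys else
    rep(FALSE, nrow(obs))
  data.frame(
    germline = !(keys %in% germline_keys),
    popfreq = obs$pop_af <= config$max_pop_af,
    depth = obs$total_depth >= config$min_depth,
    chip = !(chip_db_hit | pbl_hit)
  )
}

#' Class-specific high-quality support-read thresholds
#'
#' Tissue-derived driver mutations need >= 2 high-quality support reads;
#' tissue-derived non-driver ("nonrecurrent") mutations >= 4; ctDNA-private
#' hotspot mutations >= 4; ctDNA-private non-hotspots >= 8. Thresholds are
#' inclusive.
#'
#' @param variant_class `"tissue_derived"` or `"ctdna_private"` (vector).
#' @param is_driver,is_hotspot Logical vectors.
#' @param config A [caller_config()] carrying the threshold table.
#' @return Integer vector of required high-quality support reads.
#' @export
support_threshold <- function(variant_class, is_driver, is_hotspot,
                              config = caller_config()) {
  th <- config$thresholds
  ifelse(variant_class == "tissue_derived",
         ifelse(is_driver, th[["tissue_driver"]], th[["tissue_other"]]),
         ifelse(is_hotspot, th[["private_hotspot"]], th[["private_other"]]))
}

#' Apply the support-read thresholds
#'
#' @param classified Variant table with `variant_class` assigned (see
#'   [classify_variant()]).
#' @param config A [caller_config()].
#' @return Logical vector; TRUE where `hq_support_reads` meets the
#'   class-specific threshold.
#' @export
apply_support_thresholds <- function(classified, config = caller_config()) {
  if (is.null(classified$variant_class)) {
    stop("variant_class must be assigned before thresholding", call. = FALSE)
  }
  need <- support_threshold(classified$variant_class, classified$is_driver,
                            classified$is_hotspot, config)
  classified$hq_support_reads >= need
}

.composition_of <- function(classes) {
  has_t <- any(classes == "tissue_derived")
  has_p <- any(classes == "ctdna_private")
  if (has_t && has_p) "both"
  else if (has_t) "tissue_only"
  else if (has_p) "private_only"
  else "none"
}

#' Call MRD status for one plasma sample
#'
#' Runs the full ordered cascade on every observation: germline,
#' population-frequency and depth prefilters; CHIP filtering via the key
#' database and matched-PBL evidence; the healthy-panel background test
#' (SNVs only — indels bypass it); and the class-specific support-read
#' thresholds after tissue-derived / ctDNA-private classification. The
#' sample is MRD-positive when at least one variant passes every filter.
#'
#' @param plasma_obs Plasma variant table.
#' @param profile Matched [tissue_profile()].
#' @param background Background model ([build_background()]); may be NULL
#'   only when `config$background_test` is FALSE.
#' @param germline_keys,chip_keys,pbl_obs Filter inputs, see
#'   [apply_prefilters()].
#' @param config A [caller_config()].
#' @param patient_id,sample_id,days_from_surgery Sample identity.
#' @return An object of class `mrd_call`: `positive`, `n_passing`,
#'   `ctdna_level` (mean — or max, per config — VAF of passing variants, 0
#'   when negative), `composition` (`tissue_only`/`private_only`/`both`/
#'   `none`), and `variants`, the per-variant table with class, each filter
#'   verdict (`pass_*` columns), the background p-value, `primary_reason`
#'   (first failing filter, `"."` if passing) and `passing`.
#' @export
call_sample <- function(plasma_obs, profile, background = NULL,
                        germline_keys = character(),
                        chip_keys = character(), pbl_obs = NULL,
                        config = caller_config(),
                        patient_id = profile$patient_id,
                        sample_id = NA_character_,
                        days_from_surgery = NA_real_) {
  if (config$background_test && is.null(background) &&
      nrow(plasma_obs) > 0L && any(is_snv(plasma_obs))) {
    stop("background model required to test SNVs (or disable background_test)",
         call. = FALSE)
  }
  v <- classify_variant(plasma_obs, profile, patient_id)
  n <- nrow(v)
  if (n == 0L) {
    v <- cbind(v, data.frame(pass_germline = logical(), pass_popfreq = logical(),
                             pass_depth = logical(), pass_chip = logical(),
                             pass_background = logical(),
                             background_p = numeric(),
                             pass_support = logical(),
                             primary_reason = character(),
                             passing = logical()))
  } else {
    pre <- apply_prefilters(v, germline_keys, chip_keys, pbl_obs, config)
    snv <- is_snv(v)
    bg_p <- rep(NA_real_, n)
    pass_bg <- rep(TRUE, n)
    if (config$background_test && any(snv)) {
      res <- test_against_background(v[snv, , drop = FALSE], background,
                                     config$alpha_level)
      bg_p[snv] <- res$p_value
      pass_bg[snv] <- res$significant
    }
    pass_support <- apply_support_thresholds(v, config)
    verdicts <- cbind(germline = pre$germline, popfreq = pre$popfreq,
                      depth = pre$depth, chip = pre$chip,
                      background = pass_bg, support = pass_support)
    passing <- rowSums(!verdicts) == 0L
    first_fail <- apply(verdicts, 1L, function(row) {
      i <- which(!row)
      if (length(i) == 0L) "." else .FILTER_ORDER[i[1L]]
    })
    v$pass_germline <- pre$germline
    v$pass_popfreq <- pre$popfreq
    v$pass_depth <- pre$depth
    v$pass_chip <- pre$chip
    v$pass_background <- pass_bg
    v$background_p <- bg_p
    v$pass_support <- pass_support
    v$primary_reason <- first_fail
    v$passing <- passing
  }
  pass <- v[v$passing, , drop = FALSE]
  level <- if (nrow(pass) == 0L) 0 else
    switch(config$level_stat, mean = mean(pass$vaf), max = max(pass$vaf))
  structure(list(
    patient_id = patient_id, sample_id = sample_id,
    days_from_surgery = days_from_surgery,
    positive = nrow(pass) > 0L, n_passing = nrow(pass),
    ctdna_level = level, composition = .composition_of(pass$variant_class),
    variants = v
  ), class = "mrd_call")
}

#' @export
print.mrd_call <- function(x, ...) {
  cat(sprintf("mrd_call %s/%s (day %s): %s, %d passing variant(s), level %.4g\n",
              x$patient_id, x$sample_id, format(x$days_from_surgery),
              if (x$positive) "POSITIVE" else "negative",
              x$n_passing, x$ctdna_level))
  invisible(x)
}

#' Call MRD status for every plasma sample in a cohort
#'
#' For each patient, derives the tissue profile from the tissue sample,
#' germline keys from the matched PBL sample (variants at PBL VAF >= 0.25,
#' the germline-allele range) and CHIP evidence from the remaining PBL
#' variants, then calls every plasma sample.
#'
#' @param cohort An `mrd_cohort` from [read_cohort()].
#' @param background A `background_model`.
#' @param chip_keys Optional CHIP key database.
#' @param config A [caller_config()].
#' @param germline_vaf_min PBL VAF at or above which a PBL variant is
#'   treated as germline rather than CHIP (default 0.25).
#' @return List of `mrd_call`, one per plasma sample, in cohort order.
#' @export
call_cohort <- function(cohort, background, chip_keys = character(),
                        config = caller_config(), germline_vaf_min = 0.25) {
  calls <- list()
  for (p in cohort$patients) {
    prof <- tissue_profile(p$patient_id, p$tissue)
    germ <- character()
    pbl_somatic <- NULL
    if (!is.null(p$pbl) && nrow(p$pbl) > 0L) {
      is_germ <- p$pbl$vaf >= germline_vaf_min
      germ <- variant_key(p$pbl[is_germ, , drop = FALSE])
      pbl_somatic <- p$pbl[!is_germ, , drop = FALSE]
    }
    for (s in p$plasma) {
      calls[[length(calls) + 1L]] <- call_sample(
        s$variants, prof, background, germ, chip_keys, pbl_somatic, config,
        patient_id = p$patient_id, sample_id = s$sample_id,
        days_from_surgery = s$days_from_surgery)
    }
  }
  calls
}
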