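# Landmark status, longitudinal status, lead time and adjuvant-therapy
# clearance trajectories from serial MRD calls plus the clinical timeline.

#' Select the landmark call
#'
#' The landmark time point is 1 month (+/- 7 days) after surgery, i.e. the
#' window `[23, 37]` days by default. When several samples fall in the
#' window the earliest wins.
#'
#' @param calls Time-ordered list of `mrd_call`.
#' @param window_lo_days,window_hi_days Window bounds, inclusive.
#' @return The selected `mrd_call`, or NULL when no sample falls in the
#'   window (landmark status "unsampled").
#' @export
assign_landmark <- function(calls, window_lo_days = 23, window_hi_days = 37) {
  if (window_lo_days > window_hi_days) {
    stop("window_lo_days > window_hi_days", call. = FALSE)
  }
  days <- vapply(calls, function(cl) as.numeric(cl$days_from_surgery),
                 numeric(1))
  inw <- which(days >= window_lo_days & days <= window_hi_days)
  if (length(inw) == 0L) return(NULL)
  calls[[inw[which.min(days[inw])]]]
}

.eligible_calls <- function(calls, recurrence_day) {
  # monitoring ends at recurrence, recurrence time point inclusive
  if (is.na(recurrence_day)) return(calls)
  days <- vapply(calls, function(cl) as.numeric(cl$days_from_surgery),
                 numeric(1))
  calls[days <= recurrence_day]
}

#' Longitudinal MRD status
#'
#' Positive iff any eligible call is positive, where eligible means taken on
#' or before the recurrence day (all calls for non-recurrent patients).
#' Samples drawn after recurrence carry no surveillance information and are
#' excluded.
#'
#' @param calls Time-ordered list of `mrd_call` (at least one).
#' @param recurrence_day Recurrence day or `NA`.
#' @return `"positive"` or `"negative"`.
#' @export
longitudinal_status <- function(calls, recurrence_day = NA) {
  if (length(calls) == 0L) {
    stop("longitudinal status needs at least one call", call. = FALSE)
  }
  elig <- .eligible_calls(calls, recurrence_day)
  pos <- any(vapply(elig, function(cl) isTRUE(cl$positive), logical(1)))
  if (pos) "positive" else "negative"
}

#' Lead time from first ctDNA positivity to radiologic recurrence
#'
#' `(recurrence_day - day of first positive eligible call) / 30.4375`
#' months, floored at 0. Only defined for recurrent patients with a
#' positive eligible call.
#'
#' @param calls Time-ordered list of `mrd_call`.
#' @param recurrence_day Recurrence day (must be non-missing for a value).
#' @return Lead time in months, or `NA` when undefined.
#' @export
lead_time <- function(calls, recurrence_day) {
  if (is.na(recurrence_day)) return(NA_real_)
  elig <- .eligible_calls(calls, recurrence_day)
  pos_days <- vapply(elig[vapply(elig, function(cl) isTRUE(cl$positive),
                                 logical(1))],
                     function(cl) as.numeric(cl$days_from_surgery),
                     numeric(1))
  if (length(pos_days) == 0L) return(NA_real_)
  max(days_to_months(recurrence_day - min(pos_days)), 0)
}

#' Build a patient record from calls and the clinical row
#'
#' Derives DFS (time to first radiologic recurrence, censored at last
#' follow-up), OS (time to death, censored at last follow-up), landmark
#' status (positive / negative / unsampled), longitudinal status and lead
#' time.
#'
#' @param clinical_row One-row `data.frame` from [read_clinical()].
#' @param calls Time-ordered list of this patient's `mrd_call`s.
#' @param window_lo_days,window_hi_days Landmark window (see
#'   [assign_landmark()]).
#' @return Object of class `patient_record`.
#' @export
build_patient_record <- function(clinical_row, calls,
                                 window_lo_days = 23, window_hi_days = 37) {
  rec_day <- clinical_row$recurrence_day
  death_day <- clinical_row$death_day
  fup <- clinical_row$last_followup_day
  dfs_event <- !is.na(rec_day)
  os_event <- !is.na(death_day)
  lm <- assign_landmark(calls, window_lo_days, window_hi_days)
  lm_status <- if (is.null(lm)) "unsampled" else
    if (lm$positive) "positive" else "negative"
  lg_status <- if (length(calls) > 0L)
    longitudinal_status(calls, rec_day) else NA_character_
  lt <- if (dfs_event && identical(lg_status, "positive"))
    lead_time(calls, rec_day) else NA_real_
  structure(list(
    patient_id = clinical_row$patient_id,
    clinical = clinical_row,
    calls = calls,
    landmark_call = lm,
    landmark_status = lm_status,
    longitudinal_status = lg_status,
    dfs_days = if (dfs_event) rec_day else fup,
    dfs_event = dfs_event,
    os_days = if (os_event) death_day else fup,
    os_event = os_event,
    lead_time_months = lt
  ), class = "patient_record")
}

#' Build patient records for a whole cohort
#'
#' @param cohort An `mrd_cohort`.
#' @param calls List of `mrd_call` (e.g. from [call_cohort()]).
#' @param window_lo_days,window_hi_days Landmark window.
#' @return Named list of `patient_record`, one per clinical row.
#' @export
build_patient_records <- function(cohort, calls, window_lo_days = 23,
                                  window_hi_days = 37) {
  by_patient <- split(calls, vapply(calls, `[[`, character(1), "patient_id"))
  records <- list()
  for (i in seq_len(nrow(cohort$clinical))) {
    row <- cohort$clinical[i, , drop = FALSE]
    pc <- by_patient[[row$patient_id]]
    if (is.null(pc)) pc <- list()
    ord <- order(vapply(pc, function(cl) as.numeric(cl$days_from_surgery),
                        numeric(1)))
    records[[row$patient_id]] <- build_patient_record(
      row, pc[ord], window_lo_days, window_hi_days)
  }
  records
}

#' Per-patient summary table
#'
#' @param records List of `patient_record`.
#' @return `data.frame` with one row per patient: statuses, DFS/OS times
#'   and events, lead time (months) and clinical covariates used downstream.
#' @export
patient_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      patient_id = r$patient_id,
      stage = r$clinical$stage,
      histology = r$clinical$histology,
      lymph_node_involved = r$clinical$lymph_node_involved,
      adjuvant = r$clinical$adjuvant,
      landmark_status = r$landmark_status,
      longitudinal_status = r$longitudinal_status,
      dfs_days = r$dfs_days, dfs_event = r$dfs_event,
      os_days = r$os_days, os_event = r$os_event,
      lead_time_months = r$lead_time_months,
      stringsAsFactors = FALSE)
  }))
}

.phase_of <- function(days, start_day, end_day, endpoint_day) {
  ifelse(days >= endpoint_day, "endpoint",
         ifelse(days < start_day, "pre_adjuvant",
                ifelse(days <= end_day, "during_adjuvant", "post_adjuvant")))
}

#' Classify the ctDNA clearance trajectory around adjuvant therapy
#'
#' Calls are bucketed into pre-adjuvant, during-adjuvant, post-adjuvant and
#' endpoint (the recurrence sample for recurrent patients, else the last
#' follow-up sample) phases; each sampled phase takes the positivity of its
#' latest call and the corresponding ctDNA level. Decision table, applied
#' in order:
#' \itemize{
#'   \item no pre-adjuvant sample, or no sampled later phase: `not_evaluable`
#'   \item no phase positive: `never_positive`
#'   \item pre-adjuvant positive, every later sampled phase negative:
#'     `cleared_durable`
#'   \item a later negative phase followed by a positive one (the signal
#'     cleared, then returned): `cleared_then_regained`
#'   \item otherwise (positivity persists through/after therapy, or emerges
#'     without ever having cleared): `persistent_or_rising`
#' }
#'
#' @param record A `patient_record` (therapy days are read from its clinical
#'   row unless overridden).
#' @param therapy_start_day,therapy_end_day Adjuvant therapy window.
#' @return Object of class `clearance_trajectory`: `patient_id`,
#'   `phase_calls` (`data.frame` phase/positive/level) and `category`.
#' @export
classify_trajectory <- function(record,
                                therapy_start_day = record$clinical$adjuvant_start_day,
                                therapy_end_day = record$clinical$adjuvant_end_day) {
  out <- function(category, phases) {
    structure(list(patient_id = record$patient_id, phase_calls = phases,
                   category = category), class = "clearance_trajectory")
  }
  empty <- data.frame(phase = character(), positive = logical(),
                      level = numeric(), stringsAsFactors = FALSE)
  if (is.na(therapy_start_day) || is.na(therapy_end_day) ||
      length(record$calls) == 0L) {
    return(out("not_evaluable", empty))
  }
  rec_day <- record$clinical$recurrence_day
  endpoint_day <- if (!is.na(rec_day)) rec_day else
    max(vapply(record$calls, function(cl) as.numeric(cl$days_from_surgery),
               numeric(1)))
  days <- vapply(record$calls, function(cl) as.numeric(cl$days_from_surgery),
                 numeric(1))
  phase <- .phase_of(days, therapy_start_day, therapy_end_day, endpoint_day)
  pos <- vapply(record$calls, function(cl) isTRUE(cl$positive), logical(1))
  lev <- vapply(record$calls, function(cl) as.numeric(cl$ctdna_level),
                numeric(1))
  phase_order <- c("pre_adjuvant", "during_adjuvant", "post_adjuvant",
                   "endpoint")
  phases <- do.call(rbind, lapply(phase_order, function(ph) {
    i <- which(phase == ph)
    if (length(i) == 0L) return(NULL)
    i <- i[which.max(days[i])]   # latest call represents the phase
    data.frame(phase = ph, positive = pos[i], level = lev[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(phases)) phases <- empty
  sampled <- phases$phase
  if (!"pre_adjuvant" %in% sampled || length(sampled) < 2L) {
    return(out("not_evaluable", phases))
  }
  if (!any(phases$positive)) return(out("never_positive", phases))
  pre_pos <- phases$positive[phases$phase == "pre_adjuvant"]
  later <- phases$positive[phases$phase != "pre_adjuvant"]
  if (pre_pos) {
    first_neg <- if (any(!later)) min(which(!later)) else NA_integer_
    if (is.na(first_neg)) return(out("persistent_or_rising", phases))
    if (any(later[seq_along(later) > first_neg])) {
      return(out("cleared_then_regained", phases))
    }
    return(out("cleared_durable", phases))
  }
  # pre-adjuvant negative but a later phase positive: the signal emerged
  # without ever having cleared
  out("persistent_or_rising", phases)
}

#' @export
print.clearance_trajectory <- function(x, ...) {
  cat(sprintf("clearance_trajectory %s: %s\n", x$patient_id, x$category))
  invisible(x)
}

#' Write the per-patient longitudinal summary
#'
#' @param records List of `patient_record`.
#' @param path Output TSV path.
#' @param trajectories Optional list of `clearance_trajectory` aligned with
#'   `records` (categories are joined in when given).
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(records, path, trajectories = NULL) {
  tab <- patient_table(records)
  if (!is.null(trajectories)) {
    tr <- data.frame(
      patient_id = vapply(trajectories, `[[`, character(1), "patient_id"),
      trajectory = vapply(trajectories, `[[`, character(1), "category"),
      stringsAsFactors = FALSE)
    tab <- merge(tab, tr, by = "patient_id", all.x = TRUE, sort = FALSE)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
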