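# Reading, validating and writing variant tables and cohort bundles.
#
# All coordinates are 1-based, VCF convention. Indels are taken as given
# (left-aligned by the upstream caller); plasma/tissue matching is by the
# exact (chrom, pos, ref, alt) key, so both inputs must share one convention.

#' Columns of a variant observation table
#'
#' A variant table is a plain `data.frame` with one row per observed variant.
#' Required columns: `chrom`, `pos`, `ref`, `alt`, `total_depth`,
#' `support_reads`, `hq_support_reads`. Optional columns with defaults:
#' `vaf` (recomputed as `support_reads/total_depth`), `pop_af` (0: a variant
#' without a population-frequency annotation is never excludable on
#' frequency), `is_hotspot` (FALSE), `is_driver` (FALSE), `gene` (`NA`).
#'
#' @format A character vector of canonical column names.
#' @keywords internal
#' @export
variant_columns <- c(
  "chrom", "pos", "ref", "alt", "total_depth", "support_reads",
  "hq_support_reads", "vaf", "pop_af", "is_hotspot", "is_driver", "gene"
)

.variant_required <- c(
  "chrom", "pos", "ref", "alt", "total_depth", "support_reads",
  "hq_support_reads"
)

#' Exact variant key
#'
#' @param x A variant table (`data.frame`) or a data.frame-like object with
#'   `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector `"chrom:pos:ref:alt"`, the exact key used to match
#'   plasma variants against tissue, germline, PBL and CHIP sets.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Is a variant a single-nucleotide variant?
#'
#' @param x A variant table.
#' @return Logical vector; TRUE where both alleles are single bases.
#' @export
is_snv <- function(x) {
  nchar(x$ref) == 1L & nchar(x$alt) == 1L
}

#' Validate a variant table against its invariants
#'
#' Checks, row by row: `0 <= hq_support_reads <= support_reads <= total_depth`;
#' `vaf == support_reads/total_depth` (within 1e-6) when depth > 0;
#' `pos >= 1`; `ref != alt`; alleles nonempty; `pop_af`, `vaf` in `[0, 1]`.
#'
#' @param df A variant table.
#' @param context Label used in error messages (e.g. the file path).
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending rows.
#' @export
validate_variant_table <- function(df, context = "variant table") {
  missing_cols <- setdiff(.variant_required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("pos", "total_depth", "support_reads", "hq_support_reads")) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("%s: column '%s' is not numeric", context, col),
           call. = FALSE)
    }
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      stop(sprintf("%s: %s at row(s) %s", context, what,
                   paste(utils::head(rows, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(is.na(df$pos) | df$pos < 1, "pos < 1 or missing")
  bad(is.na(df$ref) | is.na(df$alt) | !nzchar(df$ref) | !nzchar(df$alt),
      "empty allele")
  bad(df$ref == df$alt, "ref equals alt")
  bad(is.na(df$total_depth) | is.na(df$support_reads) |
        is.na(df$hq_support_reads), "missing depth/support count")
  bad(df$hq_support_reads < 0 | df$hq_support_reads > df$support_reads |
        df$support_reads > df$total_depth,
      "violated 0 <= hq_support_reads <= support_reads <= total_depth")
  bad(df$pop_af < 0 | df$pop_af > 1, "pop_af outside [0, 1]")
  if (any(df$total_depth > 0)) {
    expect_vaf <- ifelse(df$total_depth > 0,
                         df$support_reads / df$total_depth, 0)
    bad(df$total_depth > 0 & abs(df$vaf - expect_vaf) > 1e-6,
        "vaf inconsistent with support_reads/total_depth")
  }
  invisible(df)
}

.complete_variant_table <- function(df) {
  n <- nrow(df)
  if (is.null(df$pop_af)) df$pop_af <- numeric(n)
  df$pop_af[is.na(df$pop_af)] <- 0
  if (is.null(df$is_hotspot)) df$is_hotspot <- logical(n)
  df$is_hotspot[is.na(df$is_hotspot)] <- FALSE
  if (is.null(df$is_driver)) df$is_driver <- logical(n)
  df$is_driver[is.na(df$is_driver)] <- FALSE
  if (is.null(df$gene)) df$gene <- rep(NA_character_, n)
  df$vaf <- ifelse(df$total_depth > 0, df$support_reads / df$total_depth, 0)
  df$chrom <- as.character(df$chrom)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$pos <- as.integer(df$pos)
  df$total_depth <- as.integer(df$total_depth)
  df$support_reads <- as.integer(df$support_reads)
  df$hq_support_reads <- as.integer(df$hq_support_reads)
  df$is_hotspot <- as.logical(df$is_hotspot)
  df$is_driver <- as.logical(df$is_driver)
  df[, variant_columns, drop = FALSE]
}

.flag01 <- function(x) {
  # accept TRUE/FALSE, 0/1, "true"/"false" spellings in TSV input
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a variant table (TSV or VCF)
#'
#' The TSV dialect is tab-separated with a header row carrying at least the
#' required columns (see [variant_columns]). The VCF dialect reads a
#' single-sample VCF subset: `CHROM/POS/REF/ALT`, FORMAT `AD` (ref,alt depths)
#' and `DP`, and INFO keys `POPAF`, `HOTSPOT`, `DRIVER`. VCF records carry no
#' high-quality support count, so `hq_support_reads` defaults to
#' `support_reads` there.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A validated variant table, rows in file order.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("variant file not found: %s", path), call. = FALSE)
  }
  df <- switch(dialect,
               tsv = .read_variant_tsv(path),
               vcf = .read_variant_vcf(path))
  validate_variant_table(df, context = path)
  df
}

.read_variant_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.variant_required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & nzchar(raw[[col]]) & is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric value in column '%s' at row(s) %s",
                   path, col, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    v
  }
  df <- data.frame(
    chrom = raw$chrom, pos = num("pos"), ref = raw$ref, alt = raw$alt,
    total_depth = num("total_depth"), support_reads = num("support_reads"),
    hq_support_reads = num("hq_support_reads"),
    stringsAsFactors = FALSE
  )
  if ("pop_af" %in% names(raw)) df$pop_af <- num("pop_af")
  if ("is_hotspot" %in% names(raw)) df$is_hotspot <- .flag01(raw$is_hotspot)
  if ("is_driver" %in% names(raw)) df$is_driver <- .flag01(raw$is_driver)
  if ("gene" %in% names(raw)) df$gene <- raw$gene
  .complete_variant_table(df)
}

.read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  if (is.null(ad) || ncol(ad) < 1L) {
    stop(sprintf("%s: VCF has no sample AD field", path), call. = FALSE)
  }
  ad1 <- strsplit(ad[, 1L], ",", fixed = TRUE)
  support <- vapply(ad1, function(x) {
    if (length(x) < 2L) return(NA_real_)
    suppressWarnings(as.numeric(x[[2L]]))
  }, numeric(1))
  depth <- suppressWarnings(as.numeric(dp[, 1L]))
  info <- fix$INFO
  if (is.null(info)) info <- rep("", n)
  info_value <- function(key) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    out <- rep(NA_character_, n)
    hit <- grepl(pat, info)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(pat, info)))
    out
  }
  info_flag <- function(key) {
    grepl(paste0("(^|;)", key, "(=|;|$)"), info) &
      !grepl(paste0("(^|;)", key, "=0(;|$)"), info)
  }
  pop_af <- suppressWarnings(as.numeric(info_value("POPAF")))
  hotspot <- info_flag("HOTSPOT")
  driver <- info_flag("DRIVER")
  gene <- info_value("GENE")
  df <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = fix$REF,
    alt = fix$ALT, total_depth = depth, support_reads = support,
    hq_support_reads = support, pop_af = pop_af,
    is_hotspot = hotspot, is_driver = driver, gene = gene,
    stringsAsFactors = FALSE
  )
  .complete_variant_table(df)
}

#' Write a variant table as TSV
#'
#' @param df A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  df <- .complete_variant_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with columns `patient_id`, `sample_id`, `material`
#' (`plasma`, `tissue`, `pbl` or `healthy_plasma`), `days_from_surgery`,
#' `variant_file` (path relative to the manifest unless absolute).
#' Plasma samples must be postoperative (`days_from_surgery >= 0`).
#'
#' @param path Manifest path.
#' @return A `data.frame`, one row per sample.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("patient_id", "sample_id", "material", "days_from_surgery",
           "variant_file")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop(sprintf("%s: duplicate sample_id: %s", path,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  ok_mat <- c("plasma", "tissue", "pbl", "healthy_plasma")
  if (!all(df$material %in% ok_mat)) {
    stop(sprintf("%s: material must be one of %s", path,
                 paste(ok_mat, collapse = "/")), call. = FALSE)
  }
  neg <- df$material == "plasma" & df$days_from_surgery < 0
  if (any(neg, na.rm = TRUE)) {
    stop(sprintf("%s: plasma sample(s) with negative days_from_surgery: %s",
                 path, paste(df$sample_id[which(neg)], collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read a clinical table
#'
#' Tab-separated, one row per patient: `patient_id`, `stage` (0/I/II/III,
#' optional substage suffix), `histology`, `surgery_day` (the day-0
#' reference), `recurrence_day`, `death_day`, `last_followup_day`
#' (integer days from surgery; recurrence/death may be empty), `adjuvant`
#' (`none`, `chemo`, `targeted`, `chemo_immuno`, `other`),
#' `adjuvant_start_day`, `adjuvant_end_day`, `lymph_node_involved`,
#' `smoking`.
#'
#' @param path Clinical table path.
#' @return A `data.frame`, one row per patient.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("patient_id", "stage", "histology", "surgery_day",
           "recurrence_day", "death_day", "last_followup_day", "adjuvant")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop(sprintf("%s: duplicate patient_id", path), call. = FALSE)
  }
  if (any(is.na(df$surgery_day))) {
    stop(sprintf("%s: clinical row without surgery reference: %s", path,
                 paste(df$patient_id[is.na(df$surgery_day)], collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("recurrence_day", "death_day", "last_followup_day")) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("%s: negative %s", path, col), call. = FALSE)
    }
  }
  both <- !is.na(df$recurrence_day) & !is.na(df$last_followup_day)
  if (any(df$recurrence_day[both] > df$last_followup_day[both])) {
    stop(sprintf("%s: recurrence_day after last_followup_day", path),
         call. = FALSE)
  }
  if (!"lymph_node_involved" %in% names(df)) df$lymph_node_involved <- NA
  df$lymph_node_involved <- .flag01(df$lymph_node_involved)
  if (!"smoking" %in% names(df)) df$smoking <- NA_character_
  if (!"adjuvant_start_day" %in% names(df)) df$adjuvant_start_day <- NA_real_
  if (!"adjuvant_end_day" %in% names(df)) df$adjuvant_end_day <- NA_real_
  df
}

#' Read a cohort bundle
#'
#' Joins a sample manifest to a clinical table and loads every per-sample
#' variant file. Plasma samples are attached to their patient sorted by
#' `days_from_surgery`; tissue and PBL samples are attached by material.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param clinical_path Path to the clinical TSV.
#' @param dialect Variant file dialect, `"tsv"` or `"vcf"`.
#' @return An object of class `mrd_cohort`: a list with `clinical` (the
#'   clinical `data.frame`) and `patients`, a named list holding, per patient,
#'   `plasma` (list of samples, each `list(sample_id, days_from_surgery,
#'   variants)`), `tissue` and `pbl` (variant tables or NULL).
#' @export
read_cohort <- function(manifest_path, clinical_path, dialect = "tsv") {
  manifest <- read_manifest(manifest_path)
  clinical <- read_clinical(clinical_path)
  unknown <- setdiff(manifest$patient_id, clinical$patient_id)
  if (length(unknown) > 0L) {
    stop(sprintf("manifest references patient(s) absent from clinical table: %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  base_dir <- dirname(manifest_path)
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }
  patients <- list()
  for (pid in clinical$patient_id) {
    rows <- manifest[manifest$patient_id == pid, , drop = FALSE]
    plasma <- list()
    tissue <- NULL
    pbl <- NULL
    if (nrow(rows) > 0L) {
      rows <- rows[order(rows$days_from_surgery), , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        vt <- read_variant_table(resolve(rows$variant_file[i]), dialect)
        if (rows$material[i] == "plasma") {
          plasma[[length(plasma) + 1L]] <- list(
            sample_id = rows$sample_id[i],
            days_from_surgery = rows$days_from_surgery[i],
            variants = vt
          )
        } else if (rows$material[i] == "tissue") {
          tissue <- vt
        } else if (rows$material[i] == "pbl") {
          pbl <- vt
        }
      }
    }
    patients[[pid]] <- list(patient_id = pid, plasma = plasma,
                            tissue = tissue, pbl = pbl)
  }
  no_samples <- setdiff(clinical$patient_id, manifest$patient_id)
  if (length(no_samples) > 0L) {
    message(sprintf("note: %d clinical patient(s) without any sample",
                    length(no_samples)))
  }
  structure(list(clinical = clinical, patients = patients),
            class = "mrd_cohort")
}

#' @export
print.mrd_cohort <- function(x, ...) {
  n_plasma <- sum(vapply(x$patients, function(p) length(p$plasma), integer(1)))
  cat(sprintf("mrd_cohort: %d patients, %d plasma samples\n",
              nrow(x$clinical), n_plasma))
  invisible(x)
}

#' Write MRD call reports
#'
#' Writes two TSVs under `dir`: `call_variants.tsv` with one row per
#' (sample, variant) carrying the class, every filter verdict, the primary
#' rejection reason (the first failing filter in the fixed order
#' germline, population-frequency, depth, CHIP, background, support) and the
#' passing flag; and `call_samples.tsv`, the machine-readable per-sample
#' summary (positivity, number of passing variants, ctDNA level,
#' composition). Column order is fixed, so identical calls yield
#' byte-identical reports.
#'
#' @param calls A list of `mrd_call` objects (see [call_sample()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_call_report <- function(calls, dir) {
  if (length(calls) == 0L) stop("no calls to report", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  var_rows <- do.call(rbind, lapply(calls, function(cl) {
    v <- cl$variants
    if (is.null(v) || nrow(v) == 0L) return(NULL)
    cbind(data.frame(patient_id = cl$patient_id, sample_id = cl$sample_id,
                     days_from_surgery = cl$days_from_surgery,
                     stringsAsFactors = FALSE),
          v)
  }))
  samp_rows <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(patient_id = cl$patient_id, sample_id = cl$sample_id,
               days_from_surgery = cl$days_from_surgery,
               positive = cl$positive, n_passing = cl$n_passing,
               ctdna_level = cl$ctdna_level, composition = cl$composition,
               stringsAsFactors = FALSE)
  }))
  vp <- file.path(dir, "call_variants.tsv")
  sp <- file.path(dir, "call_samples.tsv")
  if (is.null(var_rows)) {
    var_rows <- data.frame(patient_id = character(), sample_id = character(),
                           days_from_surgery = numeric())
  }
  utils::write.table(var_rows, vp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samp_rows, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(variants = vp, samples = sp))
}

#' Read back a per-sample call summary
#'
#' @param dir Directory written by [write_call_report()].
#' @return The per-sample summary `data.frame`.
#' @export
read_call_summary <- function(dir) {
  utils::read.delim(file.path(dir, "call_samples.tsv"), sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Days-to-months conversion used in all reports
#'
#' Months are reported as `days / 30.4375` (the mean Gregorian month), so
#' reported lead times and survival durations are reproducible.
#'
#' @param days Numeric days.
#' @return Numeric months.
#' @export
days_to_months <- function(days) days / 30.4375
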