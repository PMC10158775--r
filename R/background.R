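# Per-site sequencing-error background from a healthy-plasma panel.
#
# Each targeted SNV site gets a pooled error rate and a beta-binomial
# dispersion fit across the panel samples; a global fallback entry, fitted
# across sites, covers sites never observed in the panel. Only excess
# support is evidence of ctDNA, so the test is one-sided (upper tail).

.AB_MAX <- 1e10  # alpha+beta cap: beyond this the tail is binomial to ~1e-8

# Kleinman-style method-of-moments estimate of (mean, intra-class rho)
# for grouped binomial counts x out of n. Returns c(p, rho).
.mom_betabin <- function(x, n) {
  keep <- n > 0
  x <- x[keep]; n <- n[keep]
  m <- length(x)
  N <- sum(n)
  p <- sum(x) / N
  if (m < 2L || p <= 0 || p >= 1) {
    return(c(p = p, rho = 0))
  }
  S <- sum(n * (x / n - p)^2)
  num <- S / (p * (1 - p)) - (m - 1)
  den <- N - sum(n^2) / N - (m - 1)
  rho <- if (den > 0) num / den else 0
  rho <- min(max(rho, 0), 1 - 1e-9)
  c(p = p, rho = rho)
}

.ab_from_prho <- function(p, rho) {
  ab <- if (rho <= 0) .AB_MAX else min(1 / rho - 1, .AB_MAX)
  c(alpha = p * ab, beta = (1 - p) * ab)
}

#' Build a per-site sequencing-error background model
#'
#' Pools a healthy-plasma panel per targeted site and fits, by the method of
#' moments, a beta-binomial error model at each site kept at sufficient
#' panel depth. Sites with zero observed error reads get a pseudocount of
#' 0.5 errors over the pooled depth so their upper-tail test is proper. A
#' global fallback entry is fitted across the per-site pooled counts and is
#' returned for any site absent from the panel.
#'
#' @param healthy_obs `data.frame` of per-site panel observations with
#'   columns `sample_id`, `chrom`, `pos`, `ref`, `alt`, `total_depth`,
#'   `support_reads` (one row per sample x site; sites with zero support
#'   may be included or omitted per sample — omitted rows contribute no
#'   depth, so emit all covered sites for a faithful model).
#' @param min_panel_depth Minimum summed panel depth for a site to get its
#'   own entry (default 300).
#' @return An object of class `background_model`: `sites` (a `data.frame`
#'   keyed by chrom/pos/ref/alt with `n_panel_samples`, `pooled_error_rate`,
#'   `alpha_shape`, `beta_shape`), `fallback` (one-row `data.frame`, same
#'   stats pooled across sites) and `panel_size` (number of distinct healthy
#'   samples).
#' @export
build_background <- function(healthy_obs, min_panel_depth = 300) {
  if (is.null(healthy_obs) || nrow(healthy_obs) == 0L) {
    stop("empty healthy-plasma panel", call. = FALSE)
  }
  if (min_panel_depth < 1) {
    stop("min_panel_depth must be >= 1", call. = FALSE)
  }
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "total_depth",
           "support_reads")
  missing_cols <- setdiff(req, names(healthy_obs))
  if (length(missing_cols) > 0L) {
    stop(sprintf("healthy panel: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  key <- variant_key(healthy_obs)
  pooled_x <- tapply(healthy_obs$support_reads, key, sum)
  pooled_n <- tapply(healthy_obs$total_depth, key, sum)
  n_samp <- tapply(healthy_obs$sample_id, key, function(s) length(unique(s)))
  keys <- names(pooled_x)
  keep <- pooled_n >= min_panel_depth
  if (!any(keep)) {
    stop("no panel site reaches min_panel_depth", call. = FALSE)
  }
  keys <- keys[keep]
  idx_by_key <- split(seq_along(key), key)
  site_rows <- lapply(keys, function(k) {
    idx <- idx_by_key[[k]]
    x <- healthy_obs$support_reads[idx]
    n <- healthy_obs$total_depth[idx]
    tot_x <- sum(x); tot_n <- sum(n)
    if (tot_x == 0) {
      # pseudocount: 0.5 errors over the pooled depth
      p <- 0.5 / tot_n
      rho <- 0
    } else {
      f <- .mom_betabin(x, n)
      p <- f[["p"]]; rho <- f[["rho"]]
    }
    ab <- .ab_from_prho(p, rho)
    parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
    data.frame(chrom = parts[1L], pos = as.integer(parts[2L]),
               ref = parts[3L], alt = parts[4L],
               n_panel_samples = length(unique(healthy_obs$sample_id[idx])),
               pooled_error_rate = p,
               alpha_shape = ab[["alpha"]], beta_shape = ab[["beta"]],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_rows)
  # fallback: beta-binomial across site-level pooled counts, capturing
  # site-to-site error-rate variation for sites unseen in the panel
  fx <- as.numeric(pooled_x[keep]); fn <- as.numeric(pooled_n[keep])
  tot_fx <- sum(fx); tot_fn <- sum(fn)
  if (tot_fx == 0) {
    fp <- 0.5 / tot_fn; frho <- 0
  } else {
    f <- .mom_betabin(fx, fn)
    fp <- f[["p"]]; frho <- f[["rho"]]
  }
  fab <- .ab_from_prho(fp, frho)
  fallback <- data.frame(chrom = ".", pos = 0L, ref = ".", alt = ".",
                         n_panel_samples = length(unique(healthy_obs$sample_id)),
                         pooled_error_rate = fp,
                         alpha_shape = fab[["alpha"]],
                         beta_shape = fab[["beta"]],
                         stringsAsFactors = FALSE)
  structure(list(sites = sites, fallback = fallback,
                 panel_size = length(unique(healthy_obs$sample_id))),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "background_model: %d sites from %d healthy samples (fallback rate %.3g)\n",
    nrow(x$sites), x$panel_size, x$fallback$pooled_error_rate))
  invisible(x)
}

#' Look up background entries for variant keys
#'
#' @param model A `background_model`.
#' @param keys Character vector of `chrom:pos:ref:alt` keys.
#' @return A `data.frame` with one row per key (`pooled_error_rate`,
#'   `alpha_shape`, `beta_shape`, `from_fallback`); unseen sites get the
#'   fallback entry.
#' @export
background_lookup <- function(model, keys) {
  site_keys <- variant_key(model$sites)
  idx <- match(keys, site_keys)
  out <- data.frame(
    pooled_error_rate = ifelse(is.na(idx), model$fallback$pooled_error_rate,
                               model$sites$pooled_error_rate[idx]),
    alpha_shape = ifelse(is.na(idx), model$fallback$alpha_shape,
                         model$sites$alpha_shape[idx]),
    beta_shape = ifelse(is.na(idx), model$fallback$beta_shape,
                        model$sites$beta_shape[idx]),
    from_fallback = is.na(idx)
  )
  out
}

#' Beta-binomial upper-tail probability
#'
#' `P(X >= q)` for `X ~ BetaBinomial(size, alpha, beta)`, computed by direct
#' summation of the smaller tail in log space. Reduces to the binomial tail
#' as `alpha + beta` grows.
#'
#' @param q Observed count (vectorized).
#' @param size Number of trials (vectorized).
#' @param alpha,beta Beta shape parameters (vectorized).
#' @return Upper-tail probabilities in `[0, 1]`.
#' @export
pbetabinom_upper <- function(q, size, alpha, beta) {
  n <- max(length(q), length(size), length(alpha), length(beta))
  q <- rep_len(q, n); size <- rep_len(size, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  one <- function(qi, ni, a, b) {
    if (qi <= 0) return(1)
    if (qi > ni) return(0)
    lb0 <- lbeta(a, b)
    dens <- function(k) exp(lchoose(ni, k) + lbeta(k + a, ni - k + b) - lb0)
    if (qi - 1 <= ni / 2) {
      lower <- sum(dens(0:(qi - 1)))
      min(max(1 - lower, 0), 1)
    } else {
      min(max(sum(dens(qi:ni)), 0), 1)
    }
  }
  vapply(seq_len(n), function(i) one(q[i], size[i], alpha[i], beta[i]),
         numeric(1))
}

#' Test plasma variants against the sequencing-error background
#'
#' One-sided per-site test: the p-value is the upper-tail probability of
#' observing at least `support_reads` alternate reads at `total_depth` under
#' the site's fitted beta-binomial error model (fallback entry for sites not
#' in the panel). A variant is significant when `p_value < alpha_level`.
#'
#' @param obs A variant table (one or more rows).
#' @param model A `background_model`.
#' @param alpha_level Significance level in (0, 1); default 0.01.
#' @return `data.frame` with `p_value` and `significant`, one row per
#'   observation.
#' @export
test_against_background <- function(obs, model, alpha_level = 0.01) {
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("alpha_level must be in (0, 1)", call. = FALSE)
  }
  if (any(obs$total_depth <= 0)) {
    stop("total_depth must be positive for the background test",
         call. = FALSE)
  }
  entry <- background_lookup(model, variant_key(obs))
  p <- pbetabinom_upper(obs$support_reads, obs$total_depth,
                        entry$alpha_shape, entry$beta_shape)
  data.frame(p_value = p, significant = p < alpha_level)
}

#' Serialize a background model to TSV
#'
#' One row per site plus one reserved fallback row (`chrom = "."`,
#' `pos = 0`); columns `chrom`, `pos`, `ref`, `alt`, `n_panel_samples`,
#' `pooled_error_rate`, `alpha_shape`, `beta_shape`.
#'
#' @param model A `background_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_background <- function(model, path) {
  df <- rbind(model$fallback, model$sites)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a background model from TSV
#'
#' @param path TSV written by [write_background()].
#' @return A `background_model`.
#' @export
read_background <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  fb <- df$chrom == "." & df$pos == 0
  if (!any(fb)) {
    stop(sprintf("%s: no fallback row (chrom='.', pos=0)", path),
         call. = FALSE)
  }
  structure(list(sites = df[!fb, , drop = FALSE],
                 fallback = df[fb, , drop = FALSE][1L, ],
                 panel_size = df$n_panel_samples[fb][1L]),
            class = "background_model")
}
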