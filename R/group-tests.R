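# Nonparametric and parametric group comparisons, implemented directly:
# Mann-Whitney U (exact enumeration at small n, tie-corrected normal
# approximation with continuity correction otherwise), Student's t,
# Pearson's chi-square, Fisher's exact 2x2 (full hypergeometric
# enumeration) and the Wilcoxon two-sample paired signed-rank test.

# Number of ways to pick k ranks from 1..N with each rank-sum: dynamic
# programme over ranks; returns matrix [k+1, max_sum+1] of counts.
.ranksum_counts <- function(N, k) {
  max_sum <- sum((N - k + 1):N)
  ways <- matrix(0, nrow = k + 1L, ncol = max_sum + 1L)
  ways[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (j in rev(seq_len(min(r, k)))) {
      cols <- (r + 1L):(max_sum + 1L)
      ways[j + 1L, cols] <- ways[j + 1L, cols] + ways[j, cols - r]
    }
  }
  ways
}

#' Mann-Whitney U test (two independent samples)
#'
#' Exact null enumeration of the rank-sum distribution when both samples
#' are small (combined n <= 25) and tie-free; otherwise the normal
#' approximation with tie correction and continuity correction. Two-sided.
#'
#' @param x,y Numeric samples.
#' @param exact_max Combined size at or below which the exact distribution
#'   is enumerated (default 25).
#' @return List with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])               # rank sum of x
  U <- W - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (N <= exact_max && !ties) {
    ways <- .ranksum_counts(N, n1)
    probs <- ways[n1 + 1L, ] / choose(N, n1)
    sums <- seq_along(probs) - 1L
    p_le <- sum(probs[sums <= W])
    p_ge <- sum(probs[sums >= W])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 *
      (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Student's two-sample t test (pooled variance)
#'
#' @param x,y Numeric samples.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
student_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson's chi-square test on a contingency table
#'
#' Plain Pearson statistic (no continuity correction), df = (r-1)(c-1).
#'
#' @param tab Integer matrix of counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Enumerates every table with the observed margins; the two-sided p-value
#' sums the probabilities of all tables no more probable than the observed
#' one (with a 1e-7 relative tolerance, as is conventional).
#'
#' @param tab 2x2 integer matrix.
#' @return List with `p_value` and the observed table probability.
#' @export
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), prob_observed = p_obs)
}

# distribution of the positive-rank sum V for n untied ranks: generating
# function prod_r (1 + z^r), normalized by 2^n
.signed_rank_probs <- function(n) {
  max_v <- n * (n + 1) / 2
  cnt <- numeric(max_v + 1L)
  cnt[1L] <- 1
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), cnt[seq_len(max_v + 1L - r)])
    cnt <- cnt + shifted
  }
  cnt / 2^n
}

#' Wilcoxon two-sample paired signed-rank test (two-sided)
#'
#' Zero differences are dropped; exact enumeration of the positive-rank-sum
#' distribution when the number of nonzero differences is <= 25 and their
#' absolute values are tie-free, otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param exact_max Largest n for exact enumeration (default 25).
#' @return List with `statistic` (V), `p_value`, `method`, `n_used`.
#' @export
wilcoxon_signed_rank_test <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) {
    stop("paired test needs equal-length samples", call. = FALSE)
  }
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                n_used = 0L))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    probs <- .signed_rank_probs(n)
    v_support <- seq_along(probs) - 1L
    p_le <- sum(probs[v_support <= V])
    p_ge <- sum(probs[v_support >= V])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = V, p_value = p, method = method, n_used = n)
}

#' Unified group-comparison dispatcher
#'
#' @param kind One of `"mann_whitney"`, `"t_test"`, `"chi_square"`,
#'   `"fisher_exact"`, `"wilcoxon_signed_rank"`.
#' @param x,y Samples (paired for the signed-rank test).
#' @param tab Contingency table for the categorical tests.
#' @return The corresponding test result list.
#' @export
group_tests <- function(kind = c("mann_whitney", "t_test", "chi_square",
                                 "fisher_exact", "wilcoxon_signed_rank"),
                        x = NULL, y = NULL, tab = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         mann_whitney = mann_whitney_test(x, y),
         t_test = student_t_test(x, y),
         chi_square = chi_square_test(tab),
         fisher_exact = fisher_exact_test(tab),
         wilcoxon_signed_rank = wilcoxon_signed_rank_test(x, y))
}

#' Mutation-type composition of longitudinally positive patients
#'
#' For every longitudinally positive patient, pools the passing variants of
#' all eligible positive calls (calls up to and including the recurrence
#' day) and labels the patient `tissue_only`, `private_only` or `both` by
#' the union of variant classes. Also summarizes passing-variant VAFs per
#' class (median and range).
#'
#' @param records List of `patient_record`.
#' @return Object of class `composition_summary`: `counts` and
#'   `proportions` over `c(tissue_only, private_only, both)`, `n_positive`,
#'   and `vaf_summary` (per-class median/min/max of passing VAFs).
#' @export
summarize_composition <- function(records) {
  pos <- Filter(function(r) identical(r$longitudinal_status, "positive"),
                records)
  per_patient <- vapply(pos, function(r) {
    elig <- .eligible_calls(r$calls, r$clinical$recurrence_day)
    classes <- unlist(lapply(elig, function(cl) {
      if (!isTRUE(cl$positive)) return(character())
      cl$variants$variant_class[cl$variants$passing]
    }))
    .composition_of(classes)
  }, character(1))
  counts <- c(tissue_only = sum(per_patient == "tissue_only"),
              private_only = sum(per_patient == "private_only"),
              both = sum(per_patient == "both"))
  vafs <- do.call(rbind, lapply(pos, function(r) {
    elig <- .eligible_calls(r$calls, r$clinical$recurrence_day)
    do.call(rbind, lapply(elig, function(cl) {
      v <- cl$variants[cl$variants$passing, c("variant_class", "vaf")]
      v
    }))
  }))
  vaf_summary <- if (is.null(vafs) || nrow(vafs) == 0L) NULL else
    do.call(rbind, lapply(split(vafs$vaf, vafs$variant_class), function(v) {
      data.frame(n = length(v), median_vaf = stats::median(v),
                 min_vaf = min(v), max_vaf = max(v))
    }))
  structure(list(counts = counts,
                 proportions = counts / max(length(pos), 1L),
                 n_positive = length(pos),
                 vaf_summary = vaf_summary),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf(
    "composition of %d positive patients: tissue_only %d (%s), private_only %d (%s), both %d (%s)\n",
    x$n_positive,
    x$counts[["tissue_only"]], pct1(x$proportions[["tissue_only"]]),
    x$counts[["private_only"]], pct1(x$proportions[["private_only"]]),
    x$counts[["both"]], pct1(x$proportions[["both"]])))
  invisible(x)
}

#' Composition proportions from printed counts
#'
#' @param tissue_only,private_only,both Patient counts.
#' @return Named proportions over the three categories.
#' @export
composition_from_counts <- function(tissue_only, private_only, both) {
  counts <- c(tissue_only = tissue_only, private_only = private_only,
              both = both)
  counts / sum(counts)
}
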