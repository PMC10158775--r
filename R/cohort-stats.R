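# Cohort-level analytics: contingency metrics, Kaplan-Meier / log-rank /
# Cox proportional hazards, and nonparametric group comparisons.
#
# The survival machinery is implemented from first principles (product-limit
# estimator, O-E/V log-rank, Newton-Raphson partial likelihood with Efron
# tie handling); the survival package is used only as an independent oracle
# in the test suite.

#' Contingency metrics for an MRD status against recurrence
#'
#' Positive + recurred = TP, positive + disease-free = FP, negative +
#' recurred = FN, negative + disease-free = TN. Patients whose status is
#' `unsampled` (no landmark sample) or missing are excluded. Ratios with a
#' zero denominator are reported as `NA`, never 0.
#'
#' @param tab Patient table ([patient_table()]), needing `dfs_event` and the
#'   status column.
#' @param status_field `"landmark_status"` or `"longitudinal_status"`.
#' @return Object of class `contingency_metrics`: counts `tp, fp, fn, tn`,
#'   `n_analyzed`, and proportions `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `recurrence_rate_positive`, `recurrence_rate_negative`.
#' @export
contingency <- function(tab, status_field = c("landmark_status",
                                              "longitudinal_status")) {
  status_field <- match.arg(status_field)
  st <- tab[[status_field]]
  keep <- !is.na(st) & st %in% c("positive", "negative")
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no analyzable patients", call. = FALSE)
  pos <- tab[[status_field]] == "positive"
  rec <- tab$dfs_event
  tp <- sum(pos & rec); fp <- sum(pos & !rec)
  fn <- sum(!pos & rec); tn <- sum(!pos & !rec)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n_analyzed = tp + fp + fn + tn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    recurrence_rate_positive = ratio(tp, tp + fp),
    recurrence_rate_negative = ratio(fn, fn + tn)
  ), class = "contingency_metrics")
}

#' Build a contingency object directly from 2x2 counts
#'
#' Convenience for recomputing published metrics from printed counts.
#'
#' @param tp,fp,fn,tn Cell counts.
#' @return A `contingency_metrics`, as from [contingency()].
#' @export
contingency_from_counts <- function(tp, fp, fn, tn) {
  status <- rep(c("positive", "positive", "negative", "negative"),
                c(tp, fp, fn, tn))
  event <- rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fp, fn, tn))
  contingency(data.frame(landmark_status = status, dfs_event = event,
                         stringsAsFactors = FALSE), "landmark_status")
}

#' @export
print.contingency_metrics <- function(x, ...) {
  cat(sprintf(
    "contingency (n=%d): tp=%d fp=%d fn=%d tn=%d\n  sensitivity %s, specificity %s, ppv %s, npv %s\n",
    x$n_analyzed, x$tp, x$fp, x$fn, x$tn,
    pct1(x$sensitivity), pct1(x$specificity), pct1(x$ppv), pct1(x$npv)))
  invisible(x)
}

#' Format a proportion as a percentage, one decimal, half-up
#'
#' Reports round half-up (so 0.545454... prints "54.5%", 0.8650 prints
#' "86.5%"), matching conventional clinical reporting.
#'
#' @param p Proportion in `[0, 1]` (or `NA`).
#' @param percent Append a percent sign (default TRUE).
#' @return Character.
#' @export
pct1 <- function(p, percent = TRUE) {
  if (is.na(p)) return(NA_character_)
  v <- floor(p * 1000 + 0.5) / 10
  paste0(formatC(v, format = "f", digits = 1), if (percent) "%" else "")
}

#' Round a proportion to a percentage value, one decimal, half-up
#'
#' @param p Proportion in `[0, 1]`.
#' @return Numeric percentage (e.g. 0.579 -> 57.9).
#' @export
pct1_value <- function(p) {
  ifelse(is.na(p), NA_real_, floor(p * 1000 + 0.5) / 10)
}

#' Kaplan-Meier product-limit estimator
#'
#' Censored observations at time t remain in the risk set for events at t
#' (events precede censorings at tied times). The returned step function is
#' right-continuous, non-increasing, with S(0) = 1.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators (TRUE = event, FALSE = censored).
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, first row at time 0.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  events <- as.logical(events)
  ut <- sort(unique(times))
  n <- length(times)
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & !events), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  rbind(
    data.frame(time = 0, n_risk = n, n_event = 0, n_censor = 0,
               survival = 1),
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = surv)
  )
}

#' Evaluate a KM step function
#'
#' @param km A [km_estimate()] table.
#' @param t Times at which to evaluate S(t).
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    rows <- km$time <= ti
    if (!any(rows)) 1 else km$survival[max(which(rows))]
  }, numeric(1))
}

#' Log-rank test across k groups
#'
#' The usual observed-minus-expected statistic: at each distinct event time
#' the expected events per group are allocated proportionally to the group
#' risk sets, with hypergeometric variance (tie-corrected). The statistic
#' `(O-E)' V^{-1} (O-E)` over the first k-1 groups is referred to a
#' chi-square with k-1 degrees of freedom.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param group Group labels (>= 2 nonempty groups).
#' @return List with `chi2`, `df`, `p_value`, and per-group `observed` and
#'   `expected`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.character(group)
  levels_g <- sort(unique(group))
  k <- length(levels_g)
  if (k < 2L) stop("log-rank test needs >= 2 groups", call. = FALSE)
  events <- as.logical(events)
  ev_times <- sort(unique(times[events]))
  O <- stats::setNames(numeric(k), levels_g)
  E <- stats::setNames(numeric(k), levels_g)
  V <- matrix(0, k - 1L, k - 1L)
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    d_j <- sum(times == t & events)
    n_gj <- vapply(levels_g, function(g) sum(at_risk & group == g),
                   numeric(1))
    d_gj <- vapply(levels_g, function(g) sum(times == t & events &
                                               group == g), numeric(1))
    O <- O + d_gj
    E <- E + d_j * n_gj / n_j
    if (n_j > 1) {
      p <- n_gj / n_j
      vmat <- (diag(p, nrow = k) - tcrossprod(p)) *
        d_j * (n_j - d_j) / (n_j - 1)
      V <- V + vmat[seq_len(k - 1L), seq_len(k - 1L), drop = FALSE]
    }
  }
  z <- (O - E)[seq_len(k - 1L)]
  chi2 <- if (all(abs(z) < 1e-12)) 0 else
    drop(t(z) %*% solve(V, z))
  list(chi2 = chi2, df = k - 1L,
       p_value = stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

# ---- Cox proportional hazards (Efron ties) --------------------------------

#' Fit a Cox proportional-hazards model (core)
#'
#' Newton-Raphson maximization of the Efron partial likelihood, with step
#' halving. Also returns the global score test at beta = 0 (which, for a
#' single binary covariate without ties, equals the log-rank statistic).
#'
#' @param time Follow-up times.
#' @param event Logical event indicators.
#' @param X Numeric covariate matrix (columns named).
#' @param max_iter,tol Newton iteration controls.
#' @return List: `coef`, `se`, `hazard_ratio`, `ci95_lo`, `ci95_hi`,
#'   `wald_p`, `loglik`, `score_chi2`, `score_p`, `iter`.
#' @export
cox_core <- function(time, event, X, max_iter = 50L, tol = 1e-9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  status <- as.logical(event)
  keep <- stats::complete.cases(X) & !is.na(time) & !is.na(status)
  X <- X[keep, , drop = FALSE]; time <- time[keep]; status <- status[keep]
  if (sum(status) == 0L) stop("no events: Cox model undefined", call. = FALSE)
  # center covariates for numerical stability (does not change beta)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  d0 <- .cox_derivs(rep(0, ncol(Xc)), time, status, Xc)
  score_chi2 <- drop(t(d0$U) %*% solve(d0$I, d0$U))
  beta <- rep(0, ncol(Xc))
  ll <- d0$loglik
  U <- d0$U; I <- d0$I
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- solve(I, U)
    new_beta <- beta + step
    dnew <- .cox_derivs(new_beta, time, status, Xc)
    halvings <- 0L
    while (!is.finite(dnew$loglik) || dnew$loglik < ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) {
        stop(sprintf("Cox fit did not converge (iter %d: step-halving failed; |U|=%.3g)",
                     iter, max(abs(U))), call. = FALSE)
      }
      step <- step / 2
      new_beta <- beta + step
      dnew <- .cox_derivs(new_beta, time, status, Xc)
    }
    converged <- abs(dnew$loglik - ll) < tol * (abs(ll) + tol)
    beta <- new_beta; ll <- dnew$loglik; U <- dnew$U; I <- dnew$I
    if (converged || iter >= max_iter) break
  }
  if (iter >= max_iter && max(abs(U)) > 1e-4) {
    stop(sprintf("Cox fit did not converge in %d iterations (|U|=%.3g)",
                 max_iter, max(abs(U))), call. = FALSE)
  }
  se <- sqrt(diag(solve(I)))
  if (any(abs(beta) > 15)) {
    warning("possible separation: |beta| > 15", call. = FALSE)
  }
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, se = se,
       hazard_ratio = exp(beta),
       ci95_lo = exp(beta - 1.959963984540054 * se),
       ci95_hi = exp(beta + 1.959963984540054 * se),
       wald_p = 2 * stats::pnorm(-abs(z)),
       loglik = ll,
       score_chi2 = score_chi2,
       score_p = stats::pchisq(score_chi2, df = ncol(Xc),
                               lower.tail = FALSE),
       iter = iter, n = length(time), n_event = sum(status))
}

.cox_derivs <- function(beta, time, status, X) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  loglik <- sum(eta[status])
  U <- colSums(X[status, , drop = FALSE])
  I <- matrix(0, p, p)
  for (t in sort(unique(time[status]))) {
    risk <- time >= t
    D <- time == t & status
    d <- sum(D)
    Xr <- X[risk, , drop = FALSE]; wr <- w[risk]
    S0 <- sum(wr)
    S1 <- colSums(Xr * wr)
    S2 <- crossprod(Xr * sqrt(wr))
    Xd <- X[D, , drop = FALSE]; wd <- w[D]
    s0d <- sum(wd)
    s1d <- colSums(Xd * wd)
    s2d <- crossprod(Xd * sqrt(wd))
    for (l in seq_len(d) - 1L) {
      f <- l / d
      s0l <- S0 - f * s0d
      s1l <- S1 - f * s1d
      s2l <- S2 - f * s2d
      loglik <- loglik - log(s0l)
      U <- U - s1l / s0l
      I <- I + s2l / s0l - tcrossprod(s1l / s0l)
    }
  }
  list(loglik = loglik, U = U, I = I)
}

#' Ordinal coding of pathologic stage
#'
#' Strips any substage suffix ("IIIa" -> "III") and maps 0/I/II/III to
#' 0/1/2/3.
#'
#' @param stage Character vector of stages.
#' @return Numeric ordinal stage.
#' @export
stage_ordinal <- function(stage) {
  base <- toupper(gsub("[^0IViIvV]+$", "", gsub("([0IViIvV]+).*", "\\1",
                                                as.character(stage))))
  unname(c("0" = 0, "I" = 1, "II" = 2, "III" = 3)[base])
}

.cox_covariate_matrix <- function(tab, covariates) {
  cols <- lapply(covariates, function(cv) {
    switch(cv,
      stage = stage_ordinal(tab$stage),
      histology_nonadeno = as.numeric(tolower(tab$histology) !=
                                        "adenocarcinoma"),
      lymph_node_involved = as.numeric(tab$lymph_node_involved),
      longitudinal_ctdna = as.numeric(tab$longitudinal_status == "positive"),
      landmark_ctdna = as.numeric(ifelse(tab$landmark_status == "unsampled",
                                         NA, tab$landmark_status == "positive")),
      {
        if (!cv %in% names(tab)) stop(sprintf("unknown covariate '%s'", cv),
                                      call. = FALSE)
        as.numeric(tab[[cv]])
      })
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

#' Cox regression on a patient table with univariate screening
#'
#' Covariates use the documented coding: `stage` ordinal 0-3,
#' `histology_nonadeno` (1 = not adenocarcinoma), `lymph_node_involved`,
#' `longitudinal_ctdna` / `landmark_ctdna` (1 = positive); any other name is
#' taken as a numeric column of `tab`. With
#' `selection = "univariate_first"`, each covariate is first fit alone and
#' only those with two-sided Wald p < 0.05 enter the multivariate model
#' (the screening threshold applies no multiplicity correction).
#'
#' @param tab Patient table ([patient_table()]).
#' @param covariates Character vector of covariate names.
#' @param selection `"none"` or `"univariate_first"`.
#' @param endpoint `"dfs"` (default) or `"os"`.
#' @param p_enter Univariate screening threshold (default 0.05).
#' @return Object of class `cox_fit`: `univariate` (per-covariate HR table),
#'   `selected`, and `multivariate` (a [cox_core()] result or NULL when no
#'   covariate is selected).
#' @export
cox_fit <- function(tab, covariates, selection = c("univariate_first",
                                                   "none"),
                    endpoint = c("dfs", "os"), p_enter = 0.05) {
  selection <- match.arg(selection)
  endpoint <- match.arg(endpoint)
  time <- tab[[paste0(endpoint, "_days")]]
  event <- tab[[paste0(endpoint, "_event")]]
  X <- .cox_covariate_matrix(tab, covariates)
  uni <- do.call(rbind, lapply(covariates, function(cv) {
    fit <- cox_core(time, event, X[, cv, drop = FALSE])
    data.frame(covariate = cv, hazard_ratio = unname(fit$hazard_ratio),
               ci95_lo = unname(fit$ci95_lo), ci95_hi = unname(fit$ci95_hi),
               wald_p = unname(fit$wald_p), stringsAsFactors = FALSE)
  }))
  selected <- if (selection == "univariate_first")
    uni$covariate[uni$wald_p < p_enter] else covariates
  multi <- if (length(selected) > 0L)
    cox_core(time, event, X[, selected, drop = FALSE]) else NULL
  structure(list(univariate = uni, selected = selected,
                 multivariate = multi, endpoint = endpoint),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s): univariate screen kept %s\n",
              toupper(x$endpoint),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "nothing"))
  print(x$univariate, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier curves per group with a log-rank comparison
#'
#' @param times,events,group As in [logrank_test()].
#' @return Object of class `survival_fit`: `curves` (named list of
#'   [km_estimate()] tables), `logrank_chi2`, `logrank_p`.
#' @export
survfit_groups <- function(times, events, group) {
  group <- as.character(group)
  curves <- lapply(split(seq_along(times), group), function(i) {
    km_estimate(times[i], events[i])
  })
  lr <- logrank_test(times, events, group)
  structure(list(curves = curves, logrank_chi2 = lr$chi2,
                 logrank_p = lr$p_value, df = lr$df),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("survival_fit: %d group(s); log-rank chi2=%.3f (df=%d), p=%.4g\n",
              length(x$curves), x$logrank_chi2, x$df, x$logrank_p))
  invisible(x)
}

#' Export KM curves as a step-function TSV
#'
#' @param fit A [survfit_groups()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(fit, path) {
  tab <- do.call(rbind, lapply(names(fit$curves), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE), fit$curves[[g]])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
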