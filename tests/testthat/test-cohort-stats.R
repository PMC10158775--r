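# Contingency metrics, survival engine and group comparisons, checked
# against independent oracles (hand-computed tables, the survival package,
# and base-R stats tests).

test_that("contingency metrics follow the defining ratios", {
  tab <- data.frame(
    landmark_status = c("positive", "positive", "negative", "negative",
                        "unsampled"),
    dfs_event = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  cm <- contingency(tab, "landmark_status")
  expect_equal(cm$n_analyzed, 4L)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.5)
  # all-correct cohort
  perfect <- data.frame(landmark_status = c("positive", "negative"),
                        dfs_event = c(TRUE, FALSE))
  pm <- contingency(perfect, "landmark_status")
  expect_equal(pm$sensitivity, 1)
  expect_equal(pm$specificity, 1)
  # zero denominators are NA, never 0
  allpos <- data.frame(landmark_status = rep("positive", 3),
                       dfs_event = c(TRUE, TRUE, FALSE))
  expect_true(is.na(contingency(allpos, "landmark_status")$npv))
})

test_that("contingency agrees with a naive per-patient recount on random cohorts", {
  withr::with_seed(77, {
    for (i in 1:10) {
      tab <- data.frame(
        longitudinal_status = sample(c("positive", "negative"), 40,
                                     replace = TRUE),
        dfs_event = sample(c(TRUE, FALSE), 40, replace = TRUE))
      cm <- contingency(tab, "longitudinal_status")
      # independent loop-based recount
      tp <- fp <- fn <- tn <- 0
      for (j in seq_len(nrow(tab))) {
        p <- tab$longitudinal_status[j] == "positive"
        e <- tab$dfs_event[j]
        if (p && e) tp <- tp + 1 else if (p) fp <- fp + 1
        else if (e) fn <- fn + 1 else tn <- tn + 1
      }
      expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(tp, fp, fn, tn))
      if (tp + fn > 0) expect_equal(cm$sensitivity, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(cm$specificity, tn / (tn + fp))
    }
  })
})

test_that("Kaplan-Meier matches the hand-computed product-limit table", {
  times <- c(2, 4, 4, 5, 7, 9, 9, 11, 12, 14, 15, 16)
  events <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1, 0) == 1
  km <- km_estimate(times, events)
  # hand-computed: S drops at event times 2,4,5,9,12,15
  hand <- c(`2` = 11 / 12,
            `4` = 11 / 12 * 10 / 11,
            `5` = 11 / 12 * 10 / 11 * 8 / 9,
            `9` = 11 / 12 * 10 / 11 * 8 / 9 * 5 / 7,
            `12` = 11 / 12 * 10 / 11 * 8 / 9 * 5 / 7 * 3 / 4,
            `15` = 11 / 12 * 10 / 11 * 8 / 9 * 5 / 7 * 3 / 4 * 1 / 2)
  for (t in names(hand)) {
    expect_equal(km$survival[km$time == as.numeric(t)], unname(hand[t]),
                 tolerance = 1e-12)
  }
  expect_equal(km$survival[km$time == 0], 1)
  expect_true(all(diff(km$survival) <= 0))
  # independent oracle: the survival package
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  expect_equal(km_survival_at(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("KM equals the empirical survival function without censoring", {
  withr::with_seed(8, {
    times <- rexp(40, 0.1)
    km <- km_estimate(times, rep(TRUE, 40))
    grid <- seq(0, max(times), length.out = 25)
    expect_equal(km_survival_at(km, grid),
                 vapply(grid, function(t) mean(times > t), numeric(1)),
                 tolerance = 1e-12)
  })
  # trivial cases
  expect_equal(km_estimate(c(3, 6), c(FALSE, FALSE))$survival, c(1, 1, 1))
  expect_equal(km_estimate(c(5, 6, 7, 8),
                           c(TRUE, FALSE, FALSE, FALSE))$survival[2], 0.75)
})

test_that("log-rank reproduces survdiff, degenerates correctly and is label-invariant", {
  t1 <- c(6, 13, 21, 30, 31, 37, 38, 47, 49, 50)
  e1 <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  t2 <- c(10, 10, 12, 13, 14, 15, 16, 17, 18, 20)
  e2 <- c(1, 0, 1, 1, 1, 0, 1, 1, 1, 1)
  times <- c(t1, t2); events <- c(e1, e2) == 1
  grp <- rep(c("a", "b"), each = 10)
  lr <- logrank_test(times, events, grp)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-9)
  # invariance to relabeling
  lr2 <- logrank_test(times, events, rep(c("z", "y"), each = 10))
  expect_equal(lr2$chi2, lr$chi2, tolerance = 1e-12)
  # identical groups: chi2 = 0, p = 1
  same <- logrank_test(rep(t1, 2), rep(e1 == 1, 2),
                       rep(c("a", "b"), each = 10))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(t1, e1 == 1, rep("a", 10)), "2 groups")
})

test_that("log-rank at a single event time matches the 2x2 chi-square", {
  # one death at t=1 in group a; everyone at risk at t=1. With the
  # hypergeometric (N-1) variance convention the log-rank statistic is
  # (N-1)/N times the Pearson chi-square of the death/survival table.
  times <- c(1, 5, 5, 5, 6, 6)
  events <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  grp <- c("a", "a", "a", "b", "b", "b")
  lr <- logrank_test(times, events, grp)
  tab <- matrix(c(1, 2, 0, 3), nrow = 2)  # died/survived by group
  cs <- chi_square_test(tab)
  expect_equal(lr$chi2, cs$statistic * 5 / 6, tolerance = 1e-9)
})

test_that("Cox core matches coxph (Efron) and the score test equals log-rank", {
  skip_if_not_installed("survival")
  withr::with_seed(13, {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    times <- round(rexp(n, 0.05 * exp(0.8 * x)), 1)  # rounding makes ties
    events <- runif(n) < 0.8
  })
  fit <- cox_core(times, events, cbind(x = x))
  ref <- survival::coxph(survival::Surv(times, events) ~ x,
                         ties = "efron")
  expect_equal(unname(fit$coef), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(stats::vcov(ref)[1, 1])), tolerance = 1e-6)
  # two covariates
  withr::with_seed(14, z <- rnorm(80))
  fit2 <- cox_core(times, events, cbind(x = x, z = z))
  ref2 <- survival::coxph(survival::Surv(times, events) ~ x + z,
                          ties = "efron")
  expect_equal(unname(fit2$coef), unname(stats::coef(ref2)),
               tolerance = 1e-6)
  # untied data: global score test at beta=0 equals the log-rank statistic
  withr::with_seed(15, {
    tu <- rexp(60, 0.05 * exp(0.5 * rep(0:1, 30)))
    xu <- rep(0:1, 30)
    eu <- rep(TRUE, 60)
  })
  fit3 <- cox_core(tu, eu, cbind(x = xu))
  lr <- logrank_test(tu, eu, xu)
  expect_equal(fit3$score_chi2, lr$chi2, tolerance = 1e-6)
})

test_that("Cox interval behaves under a null covariate and screening drops it", {
  withr::with_seed(99, {
    n <- 300
    a <- rbinom(n, 1, 0.5)           # strong real effect
    b <- rbinom(n, 1, 0.5)           # no effect
    t <- rexp(n, 0.04 * exp(1.2 * a))
    cens <- rexp(n, 0.02)
    times <- pmin(t, cens); events <- t <= cens
  })
  tab <- data.frame(stage = "II", histology = "adenocarcinoma",
                    lymph_node_involved = FALSE,
                    landmark_status = "negative",
                    longitudinal_status = "negative",
                    dfs_days = times, dfs_event = events,
                    os_days = times, os_event = events,
                    a = a, b = b)
  fit <- cox_fit(tab, c("a", "b"), selection = "univariate_first")
  expect_true("a" %in% fit$selected)
  expect_false("b" %in% fit$selected)
  expect_gt(fit$univariate$wald_p[fit$univariate$covariate == "b"], 0.05)
  # null covariate fit alone: HR close to 1
  null_fit <- cox_core(times, events, cbind(b = b))
  expect_gt(null_fit$hazard_ratio, 0.75)
  expect_lt(null_fit$hazard_ratio, 1.33)
})

test_that("stage coding is ordinal and substage-insensitive", {
  expect_equal(stage_ordinal(c("0", "I", "Ib", "II", "IIa", "III", "IIIa")),
               c(0, 1, 1, 2, 2, 3, 3))
})

test_that("rank tests match their base-R oracles", {
  x <- c(1.1, 2.3, 3.1, 4.8, 5.6, 7.2)
  y <- c(0.8, 1.9, 2.2, 3.0, 3.3)
  mw <- mann_whitney_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(mw$statistic, unname(ref$statistic))
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # large-sample route against the normal-approximation oracle
  withr::with_seed(3, {
    xl <- rnorm(40); yl <- rnorm(45, 0.5)
  })
  mwl <- mann_whitney_test(xl, yl)
  refl <- stats::wilcox.test(xl, yl, exact = FALSE, correct = TRUE)
  expect_equal(mwl$p_value, refl$p.value, tolerance = 1e-9)
  # paired signed-rank, exact
  a <- c(4.2, 5.1, 6.0, 3.9, 7.7, 2.2, 5.5, 6.1)
  b <- c(3.9, 5.6, 5.15, 4.45, 6.2, 2.95, 5.05, 5.3)
  sr <- wilcoxon_signed_rank_test(a, b)
  refsr <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(sr$statistic, unname(refsr$statistic))
  expect_equal(sr$p_value, refsr$p.value, tolerance = 1e-12)
  # identical paired vectors: degenerate, p = 1
  expect_equal(wilcoxon_signed_rank_test(a, a)$p_value, 1)
  expect_error(wilcoxon_signed_rank_test(a, b[-1]), "equal-length")
})

test_that("t, chi-square and Fisher tests match their oracles", {
  withr::with_seed(4, {
    x <- rnorm(20, 1); y <- rnorm(25, 0.4)
  })
  tt <- student_t_test(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)

  tab <- matrix(c(20, 10, 12, 25), nrow = 2)
  cs <- chi_square_test(tab)
  refc <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(cs$statistic, unname(refc$statistic), tolerance = 1e-12)
  expect_equal(cs$p_value, refc$p.value, tolerance = 1e-12)

  # (3,1 / 1,3): full hypergeometric enumeration gives 34/70
  f <- fisher_exact_test(matrix(c(3, 1, 1, 3), nrow = 2, byrow = TRUE))
  expect_equal(f$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(f$p_value,
               stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               tolerance = 1e-9)
  # dispatcher routes correctly
  expect_equal(group_tests("fisher_exact", tab = matrix(c(3, 1, 1, 3), 2))$p_value,
               f$p_value)
})

test_that("Mann-Whitney holds its size under the null", {
  withr::with_seed(200, {
    p <- replicate(1000, {
      mann_whitney_test(rnorm(30), rnorm(30))$p_value
    })
  })
  # rejection rate at alpha = 0.05 within Monte-Carlo bounds
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("composition summary equals a direct per-patient recount", {
  pipe <- run_small_pipeline(seed = 33)
  cs <- summarize_composition(pipe$records)
  # independent recount straight from the call objects
  want <- c(tissue_only = 0L, private_only = 0L, both = 0L)
  n_pos <- 0L
  for (r in pipe$records) {
    if (!identical(r$longitudinal_status, "positive")) next
    n_pos <- n_pos + 1L
    rd <- r$clinical$recurrence_day
    classes <- character()
    for (cl in r$calls) {
      if (!is.na(rd) && cl$days_from_surgery > rd) next
      classes <- c(classes,
                   cl$variants$variant_class[cl$variants$passing])
    }
    ht <- "tissue_derived" %in% classes
    hp <- "ctdna_private" %in% classes
    lab <- if (ht && hp) "both" else if (ht) "tissue_only" else
      "private_only"
    want[lab] <- want[lab] + 1L
  }
  expect_equal(cs$counts, want)
  expect_equal(cs$n_positive, n_pos)
  expect_equal(sum(cs$proportions), 1, tolerance = 1e-12)
})
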