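# Classification, filter cascade and support thresholds.

no_bg <- caller_config(background_test = FALSE)

test_that("plasma variants are classified by exact tissue-key membership", {
  prof <- tissue_profile("P001", make_obs(is_driver = TRUE))
  # same key as the tissue profile -> tissue_derived, flags copied over
  got <- classify_variant(make_obs(is_driver = FALSE), prof)
  expect_equal(got$variant_class, "tissue_derived")
  expect_true(got$is_driver)
  # any key difference -> ctdna_private
  got2 <- classify_variant(make_obs(alt = "G"), prof)
  expect_equal(got2$variant_class, "ctdna_private")
  # empty profile: everything is private
  empty <- tissue_profile("P001", NULL)
  got3 <- classify_variant(rbind(make_obs(), make_obs(pos = 1)), empty)
  expect_equal(got3$variant_class, rep("ctdna_private", 2))
  # patient mismatch is an error
  expect_error(classify_variant(make_obs(), prof, patient_id = "P002"),
               "P001")
})

test_that("prefilters fail on population frequency, depth, germline and PBL evidence", {
  cfg <- caller_config()
  expect_false(apply_prefilters(make_obs(pop_af = 0.02), config = cfg)$popfreq)
  expect_true(apply_prefilters(make_obs(pop_af = 0.01), config = cfg)$popfreq)
  expect_false(apply_prefilters(make_obs(total_depth = 299),
                                config = cfg)$depth)
  expect_true(apply_prefilters(make_obs(total_depth = 300),
                               config = cfg)$depth)
  obs <- make_obs()
  expect_false(apply_prefilters(obs, germline_keys = variant_key(obs),
                                config = cfg)$germline)
  # matched PBL with >= 2 HQ support reads marks the variant as CHIP
  pbl2 <- make_obs(support_reads = 2, hq_support_reads = 2,
                   total_depth = 1000)
  expect_false(apply_prefilters(obs, pbl_obs = pbl2, config = cfg)$chip)
  pbl1 <- make_obs(support_reads = 2, hq_support_reads = 1,
                   total_depth = 1000)
  expect_true(apply_prefilters(obs, pbl_obs = pbl1, config = cfg)$chip)
  # CHIP database route
  expect_false(apply_prefilters(obs, chip_keys = variant_key(obs),
                                config = cfg)$chip)
  # both CHIP routes can be disabled
  off <- caller_config(use_chip_db = FALSE, use_pbl_filter = FALSE)
  expect_true(apply_prefilters(obs, chip_keys = variant_key(obs),
                               pbl_obs = pbl2, config = off)$chip)
})

test_that("support thresholds follow the four-way class table, inclusive", {
  cases <- expand.grid(class = c("tissue_derived", "ctdna_private"),
                       driver = c(TRUE, FALSE), hotspot = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  need <- with(cases, ifelse(class == "tissue_derived",
                             ifelse(driver, 2, 4),
                             ifelse(hotspot, 4, 8)))
  got <- support_threshold(cases$class, cases$driver, cases$hotspot)
  expect_equal(unname(got), need)
  # boundary behavior: equality passes, one fewer fails
  at <- function(class, driver, hotspot, hq) {
    obs <- make_obs(hq_support_reads = hq, support_reads = hq,
                    is_driver = driver, is_hotspot = hotspot)
    obs$variant_class <- class
    apply_support_thresholds(obs)
  }
  expect_true(at("tissue_derived", TRUE, FALSE, 2))
  expect_false(at("tissue_derived", TRUE, FALSE, 1))
  expect_false(at("tissue_derived", FALSE, FALSE, 3))
  expect_true(at("tissue_derived", FALSE, FALSE, 4))
  expect_true(at("ctdna_private", FALSE, TRUE, 4))
  expect_false(at("ctdna_private", FALSE, FALSE, 7))
  expect_true(at("ctdna_private", FALSE, FALSE, 8))
})

test_that("the full cascade agrees with a brute-force rule evaluator on an exhaustive grid", {
  grid <- expand.grid(
    in_tissue = c(TRUE, FALSE), driver = c(TRUE, FALSE),
    hotspot = c(TRUE, FALSE), hq = 0:10,
    depth = c(250L, 3000L), pop_af = c(0, 0.02),
    in_germline = c(TRUE, FALSE), pbl_hq = c(0L, 2L),
    stringsAsFactors = FALSE)
  tissue_var <- make_obs(is_driver = FALSE, is_hotspot = FALSE)
  prof <- tissue_profile("P001", tissue_var)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    obs <- make_obs(pos = if (g$in_tissue) tissue_var$pos else 999L,
                    total_depth = g$depth, support_reads = g$hq,
                    hq_support_reads = g$hq, pop_af = g$pop_af,
                    is_driver = g$driver, is_hotspot = g$hotspot)
    pbl <- if (g$pbl_hq > 0)
      make_obs(pos = obs$pos, total_depth = 1000L,
               support_reads = g$pbl_hq, hq_support_reads = g$pbl_hq)
    else NULL
    germ <- if (g$in_germline) variant_key(obs) else character()
    call <- call_sample(obs, prof, germline_keys = germ, pbl_obs = pbl,
                        config = no_bg)
    want <- brute_force_rule(g$in_tissue, g$driver, g$hotspot, g$hq,
                             g$depth, g$pop_af, g$in_germline,
                             in_chip = FALSE, pbl_hq = g$pbl_hq,
                             background_significant = TRUE)
    expect_equal(call$variants$passing, want$passing,
                 label = paste("cell", i))
    expect_equal(call$variants$primary_reason, want$reason,
                 label = paste("reason", i))
    expect_equal(call$positive, want$passing)
  }
})

test_that("calls summarize positivity, level and composition correctly", {
  prof <- tissue_profile("P001", make_obs(is_driver = TRUE))
  # nothing passes: negative, level 0, composition none
  neg <- call_sample(make_obs(support_reads = 1, hq_support_reads = 1,
                              is_driver = FALSE),
                     prof, config = caller_config(background_test = FALSE,
                                                  thresholds = c(
                                                    tissue_driver = 2L,
                                                    tissue_other = 4L,
                                                    private_hotspot = 4L,
                                                    private_other = 8L)))
  expect_false(neg$positive)
  expect_equal(neg$ctdna_level, 0)
  expect_equal(neg$composition, "none")
  # one passing tissue-derived driver: positive, tissue_only
  pos <- call_sample(make_obs(support_reads = 2, hq_support_reads = 2),
                     prof, config = no_bg)
  expect_true(pos$positive)
  expect_equal(pos$composition, "tissue_only")
  expect_equal(pos$ctdna_level, 2 / 3000)
  # one of each class: both; level is the mean of passing VAFs
  two <- call_sample(rbind(
    make_obs(support_reads = 30, hq_support_reads = 30),
    make_obs(pos = 999, support_reads = 12, hq_support_reads = 12)),
    prof, config = no_bg)
  expect_equal(two$composition, "both")
  expect_equal(two$ctdna_level, mean(c(30, 12) / 3000))
  # an indel bypasses the background test but obeys thresholds
  indel <- make_obs(pos = 777, ref = "A", alt = "ATT", support_reads = 9,
                    hq_support_reads = 9)
  ic <- call_sample(indel, prof, background = NULL,
                    config = caller_config(background_test = TRUE))
  expect_true(ic$positive)
  expect_true(is.na(ic$variants$background_p))
  # SNVs present without a model is an error when the test is enabled
  expect_error(call_sample(make_obs(), prof, background = NULL,
                           config = caller_config(background_test = TRUE)),
               "background")
})

test_that("passing is monotone in hq_support_reads", {
  prof <- tissue_profile("P001", make_obs())
  withr::with_seed(5, {
    for (i in 1:50) {
      hq <- sample(0:12, 1)
      obs <- make_obs(pos = sample(c(55249071L, 999L), 1),
                      support_reads = 12L, hq_support_reads = hq,
                      is_driver = sample(c(TRUE, FALSE), 1),
                      is_hotspot = sample(c(TRUE, FALSE), 1))
      lo <- call_sample(obs, prof, config = no_bg)$variants$passing
      obs$hq_support_reads <- obs$hq_support_reads + 1L
      obs$support_reads <- 13L
      hi <- call_sample(obs, prof, config = no_bg)$variants$passing
      expect_true(hi >= lo)
    }
  })
})

test_that("sample compositions partition any simulated call set", {
  pipe <- run_small_pipeline(seed = 21)
  comp <- vapply(pipe$calls, `[[`, character(1), "composition")
  expect_equal(sum(table(factor(comp, levels = c("tissue_only",
                                                 "private_only", "both",
                                                 "none")))),
               length(pipe$calls))
  # composition agrees with the classes of passing variants in every call
  for (cl in pipe$calls) {
    classes <- cl$variants$variant_class[cl$variants$passing]
    want <- if (length(classes) == 0) "none"
    else if (all(classes == "tissue_derived")) "tissue_only"
    else if (all(classes == "ctdna_private")) "private_only"
    else "both"
    expect_equal(cl$composition, want)
    expect_equal(cl$positive, length(classes) > 0)
  }
})
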