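test_that("the generator is deterministic and stable under case-count growth", {
  cfg <- cohort_config(n_cases = c(pos_concordant = 5, pos_discordant = 5,
                                   neg_concordant = 5, neg_discordant = 2),
                       seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # per-case streams are split from the global seed by counter, so the
  # first cases of a larger cohort are unchanged
  cfg2 <- cohort_config(n_cases = c(pos_concordant = 8, pos_discordant = 5,
                                    neg_concordant = 5, neg_discordant = 2),
                        seed = 31)
  c2 <- generate_cohort(cfg2)
  expect_identical(
    a$nuclei[a$nuclei$sample_id == "pos_concordant_0001", ],
    c2$nuclei[c2$nuclei$sample_id == "pos_concordant_0001", ])
})

test_that("an empty cohort yields schema-valid empty tables", {
  cfg <- cohort_config(n_cases = c(pos_concordant = 0, pos_discordant = 0,
                                   neg_concordant = 0, neg_discordant = 0))
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$nuclei), 0)
  expect_named(coh$nuclei, c("sample_id", "nucleus_id", "tokens",
                             "split_ok"))
  expect_equal(nrow(coh$cases), 0)
})

test_that("a pure inversion mixture classifies to [INVERSION] with and without artifacts", {
  cfg0 <- cohort_config(n_cases = c(pos_concordant = 6, pos_discordant = 0,
                                    neg_concordant = 0, neg_discordant = 0),
                        p_artifact = 0, seed = 5)
  # force the single-pattern inversion combination
  cfg0$combo_freq$concordant <- data.frame(
    combination = "inversion", subthreshold = 0L, n_samples = 1L)
  coh <- generate_cohort(cfg0)
  cls <- classify_nuclei(coh$nuclei)
  for (sid in unique(cls$sample_id)) {
    res <- summarize_fish_sample(cls[cls$sample_id == sid, ])
    expect_equal(res$pattern_set$class, "INVERSION", info = sid)
    # without artifacts every rearranged nucleus is a clean inversion
    rearr <- cls$class[cls$sample_id == sid & cls$class != "NOT_REARRANGED"]
    expect_true(all(rearr == "INVERSION"))
  }

  cfg2 <- cfg0
  cfg2$p_artifact <- 0.2
  coh2 <- generate_cohort(cfg2)
  cls2 <- classify_nuclei(coh2$nuclei)
  # sectioning now produces degraded residues...
  expect_true(any(cls2$class %in% c("INTERSTITIAL_DELETION",
                                    "THREE_PRIME_DELETION")))
  # ...but the derivation rule folds them back into a single inversion call
  for (sid in unique(cls2$sample_id)) {
    res <- summarize_fish_sample(cls2[cls2$sample_id == sid, ])
    expect_equal(res$pattern_set$class, "INVERSION", info = sid)
  }
})

test_that("pattern-class sets are recovered in at least 95% of samples", {
  cfg <- cohort_config(n_cases = c(pos_concordant = 50, pos_discordant = 50,
                                   neg_concordant = 0, neg_discordant = 0),
                       p_artifact = 0.2, seed = 11)
  coh <- generate_cohort(cfg)
  rep <- run_pipeline(coh$nuclei, coh$cases)
  pc <- dplyr::inner_join(rep$per_case, coh$truth, by = "case_id")
  derived <- strsplit(pc$pattern_set, "+", fixed = TRUE)
  ok <- mapply(setequal, derived, pc$true_classes)
  expect_gte(mean(ok), 0.95)
})

test_that("measured rearranged fractions track the generative truth", {
  cfg <- cohort_config(n_cases = c(pos_concordant = 40, pos_discordant = 40,
                                   neg_concordant = 0, neg_discordant = 0),
                       p_artifact = 0.1, seed = 23)
  coh <- generate_cohort(cfg)
  rep <- run_pipeline(coh$nuclei, coh$cases)
  pc <- dplyr::inner_join(rep$per_case, coh$truth, by = "case_id")
  mae <- mean(abs(pc$percent_rearranged / 100 -
                    pc$true_rearranged_fraction))
  se <- mean(sqrt(pc$true_rearranged_fraction *
                    (1 - pc$true_rearranged_fraction) / pc$n_enumerated))
  expect_lt(mae, 2 * se)
})

test_that("CNG categories are recovered exactly by construction", {
  cfg <- cohort_config(n_cases = c(pos_concordant = 30, pos_discordant = 30,
                                   neg_concordant = 0, neg_discordant = 0),
                       p_artifact = 0, seed = 17)
  coh <- generate_cohort(cfg)
  rep <- run_pipeline(coh$nuclei, coh$cases)
  pc <- dplyr::inner_join(rep$per_case, coh$truth, by = "case_id")
  expect_equal(pc$cng_category, pc$true_cng_category)
})

test_that("a cohort with the reference group proportions reproduces its rates", {
  cfg <- cohort_config(n_cases = c(pos_concordant = 19, pos_discordant = 3,
                                   neg_concordant = 244, neg_discordant = 2),
                       seed = 3)
  coh <- generate_cohort(cfg)
  rep <- run_pipeline(coh$nuclei, coh$cases)
  expect_equal(sum(rep$counts), 268)
  # empirical discordance rate within binomial noise of the target rate
  p_ref <- 5 / 268
  se <- sqrt(p_ref * (1 - p_ref) / 268)
  expect_lt(abs(rep$summaries$overall_discordance / 100 - p_ref), 3 * se)
  # the FISH-negative archetypes never cross the positivity cut-off
  truth <- merge(rep$per_case, coh$truth, by = "case_id")
  neg <- truth$archetype.y %in% c("neg_concordant", "neg_discordant")
  expect_true(all(truth$fish_status[neg] == "NEGATIVE"))
})
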