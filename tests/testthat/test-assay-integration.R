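test_that("IHC scoring follows the staining categories", {
  expect_equal(score_ihc("strong_3plus"), "positive")
  expect_equal(score_ihc("strong_2plus"), "positive")
  expect_equal(score_ihc("none"), "negative")
  expect_equal(score_ihc("weak_1plus"), "negative")
  expect_equal(score_ihc("stippled"), "negative")
  # dot-like positivity counts only in the reevaluation stage
  expect_equal(score_ihc("dot_like"), "negative")
  expect_equal(score_ihc("dot_like", is_reevaluation = TRUE), "positive")
  expect_error(score_ihc("granular"))
})

test_that("concordance classification covers the four-way partition", {
  expect_equal(classify_concordance("negative", "POSITIVE"), "POS_DISC")
  expect_equal(classify_concordance("positive", "NEGATIVE"), "NEG_DISC")
  expect_equal(classify_concordance("positive", "POSITIVE"), "POS_CONC")
  expect_equal(classify_concordance("negative", "NEGATIVE"), "NEG_CONC")
  expect_equal(classify_concordance("positive", "INSUFFICIENT"), "EXCLUDED")
})

test_that("the IHC reevaluation step reclassifies dot-like repeats", {
  init <- c(pos_conc = 184, pos_disc = 38, neg_disc = 17, neg_conc = 2444)
  upd <- apply_reevaluation(init, n_repeated = 9, n_dot_like = 5)
  expect_equal(upd[["pos_conc"]], 189)
  expect_equal(upd[["pos_disc"]], 33)
  expect_equal(sum(upd), sum(init))  # conservation
  expect_equal(apply_reevaluation(init, 0, 0), init)
  expect_error(apply_reevaluation(c(pos_conc = 1, pos_disc = 2,
                                    neg_disc = 0, neg_conc = 0), 3, 1),
               "more cases than are positive discordant")
  expect_error(apply_reevaluation(init, 2, 3), "more dot-like")
})

test_that("NGS QC applies each threshold with its stated strictness", {
  pass <- ngs_qc(80, 12, 45, 4, 0.5)  # DNA bound inclusive
  expect_true(pass$pass)
  expect_equal(ngs_qc(79, 12, 45, 4, 0.5)$reason, "dna_insufficient")
  expect_equal(ngs_qc(100, 10, 45, 4, 0.5)$reason, "rna_insufficient")
  expect_equal(ngs_qc(100, 12, 29, 4, 0.5)$reason, "rna_degraded")
  expect_equal(ngs_qc(100, 12, 30, 4, 0.5)$reason, "rna_degraded")
  expect_equal(ngs_qc(100, 12, 45, 3, 0.5)$reason, "library_low")
  expect_equal(ngs_qc(100, 12, 45, 4, 0.2)$reason, "low_tumor_content")
  expect_equal(ngs_qc(NA, 12, 45, 4, 0.5)$reason, "missing_data")
})

test_that("fusion calling requires five unique supporting reads", {
  ev <- tibble::tibble(partner_gene = c("EML4", "EML4", "CSFT3"),
                       unique_reads = c(12, 4, 7))
  called <- call_ngs_fusion(ev)
  expect_equal(called$partner_gene, c("EML4", "CSFT3"))
  expect_true(all(called$alk_fusion))
  expect_equal(nrow(call_ngs_fusion(ev, min_unique_reads = 13)), 0)
})

test_that("sensitivity and specificity match the reference counts", {
  m <- sensitivity_specificity(189, 33, 17, 2444)
  expect_equal(m$sensitivity, 100 * 189 / 206)
  expect_equal(round(m$sensitivity, 1), 91.7)
  expect_equal(m$specificity, 100 * 2444 / 2477, tolerance = 1e-12)
  # fully concordant cohort: both metrics 100%
  m <- sensitivity_specificity(10, 0, 0, 90)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  m <- sensitivity_specificity(0, 5, 0, 0)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$undefined, "sensitivity")
})

test_that("cohort summaries reproduce the reference discordance rates", {
  s <- cohort_summaries(c(pos_conc = 189, pos_disc = 33,
                          neg_disc = 17, neg_conc = 2444))
  expect_equal(s$n, 2683)
  expect_equal(round(s$overall_discordance, 2), 1.86)
  expect_equal(round(s$positive_discordance, 2), 1.23)
  expect_equal(round(s$negative_discordance, 2), 0.63)
  expect_equal(round(s$pos_disc_of_fish_positive, 1), 14.9)
  expect_equal(round(s$neg_disc_of_fish_negative, 1), 0.7)
  # one concordant case: no discordance
  s1 <- cohort_summaries(c(pos_conc = 1, pos_disc = 0,
                           neg_disc = 0, neg_conc = 0))
  expect_equal(s1$overall_discordance, 0)
})

test_that("ALK frequency stratification matches direct tabulation", {
  cases <- tibble::tibble(
    sex = c("M", "M", "F", "F", "F"),
    fish_status = c("POSITIVE", "NEGATIVE", "POSITIVE", "POSITIVE",
                    "NEGATIVE"))
  f <- alk_frequency_by(cases, sex)
  expect_equal(f$frequency[f$sex == "M"], 50)
  expect_equal(f$frequency[f$sex == "F"], 100 * 2 / 3)
})

test_that("CNV amplification calls use per-gene thresholds without purity scaling", {
  ev <- tibble::tibble(gene = c("ALK", "ALK", "MYC"),
                       copy_count = c(14, 13, 22))
  called <- call_ngs_cnv(ev)
  expect_equal(called$amplified, c(TRUE, FALSE, NA))
  expect_error(call_ngs_cnv(ev, tumor_content = 0.5),
               "explicit per-gene thresholds")
  called2 <- call_ngs_cnv(ev, tumor_content = 0.5,
                          thresholds = c(ALK = 6, MYC = 8))
  expect_equal(called2$amplified, c(TRUE, TRUE, TRUE))
})
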