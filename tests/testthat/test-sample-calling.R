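test_that("sample scoring applies the 15% and 50-cell rules", {
  pos <- score_sample(c(rep("INVERSION", 26), rep("NOT_REARRANGED", 74)))
  expect_equal(pos$status, "POSITIVE")
  expect_equal(pos$percent_rearranged, 26)

  neg <- score_sample(c(rep("INVERSION", 14), rep("NOT_REARRANGED", 86)))
  expect_equal(neg$status, "NEGATIVE")

  # inclusive cut-off
  expect_equal(score_sample(c(rep("TRANSLOCATION", 15),
                              rep("NOT_REARRANGED", 85)))$status,
               "POSITIVE")

  ins <- score_sample(rep("NOT_REARRANGED", 49))
  expect_equal(ins$status, "INSUFFICIENT")

  # predominantly 3' deletion: negative under guidelines, atypical flagged
  atyp <- score_sample(c(rep("THREE_PRIME_DELETION", 74),
                         rep("INVERSION", 4), rep("NOT_REARRANGED", 22)))
  expect_equal(atyp$status, "NEGATIVE")
  expect_equal(atyp$percent_rearranged, 4)
  expect_true(atyp$atypical_flag)
})

test_that("derivability is whole-token sub-multiset containment", {
  expect_true(derivable(c("O+B"), c("O+B", "G+B")))
  expect_false(derivable(c("O+B", "G+B"), c("O+B")))
  # a co-localized token cannot shed a single channel
  expect_false(derivable(c("O", "G+B"), c("O+B", "G+B")))
  # multiplicities matter
  expect_false(derivable(c("O+B", "O+B"), c("O+B")))
  expect_true(derivable(c("O+B", "O+B"), c("O+B", "O+B", "G+B")))
  expect_true(derivable(character(0), c("O")))
})

test_that("pattern-set derivation folds artifacts and orders classes", {
  # sectioning fragment folds into the predominant inversion
  ps <- derive_pattern_set(c("O+B;G+B" = 40, "O+B" = 10))
  expect_equal(ps$class, "INVERSION")
  expect_equal(ps$percent, 50)
  expect_equal(attr(ps, "folded"), "O+B")

  # three surviving classes in percentage order
  ps <- derive_pattern_set(c("O" = 30, "O;G+B" = 12, "O+B;G+B" = 6))
  expect_equal(ps$class, c("FIVE_PRIME_DELETION", "TRANSLOCATION",
                           "INVERSION"))

  # minority below 4% of rearranged nuclei is discarded
  ps <- derive_pattern_set(c("O+B;G+B" = 50, "O;G+B" = 3))
  expect_equal(ps$class, "INVERSION")
  expect_equal(attr(ps, "dropped"), "O;G+B")

  # no rearranged variants: empty set
  expect_equal(nrow(derive_pattern_set(numeric(0))), 0)
  # 3' deletion residues never enter the derivation
  expect_equal(nrow(derive_pattern_set(c("G+B" = 60, "G+B;B" = 20))), 0)
})

test_that("pattern-set derivation is idempotent and monotone", {
  reps <- class_representatives()
  start <- c("O+B" = 55, "O+B;G+B" = 30, "O;G+B" = 15)
  ps <- derive_pattern_set(start)
  # re-deriving from the folded class percentages is a fixed point
  again <- stats::setNames(
    ps$percent,
    vapply(reps[ps$class], paste, character(1), collapse = ";"))
  ps2 <- derive_pattern_set(again)
  expect_equal(ps2$class, ps$class)
  expect_equal(ps2$percent, ps$percent)

  # adding predominant-variant nuclei never changes the class set
  more_pred <- start + c(30, 0, 0)
  expect_equal(derive_pattern_set(more_pred)$class, ps$class)

  # adding a non-derivable variant can only add or promote its class
  with_new <- c(start, "O" = 10)
  ps3 <- derive_pattern_set(with_new)
  expect_true(all(ps$class %in% c(ps3$class, attr(ps3, "overflow"))))
  expect_true("FIVE_PRIME_DELETION" %in%
                c(ps3$class, attr(ps3, "overflow")))
})

test_that("predominant ties break toward more tokens then label, and are logged", {
  ps <- derive_pattern_set(c("O+B" = 40, "O+B;G+B" = 40))
  expect_equal(attr(ps, "predominant_variant"), "O+B;G+B")
  expect_true(attr(ps, "ties"))
  # the interstitial residue folds into the predominant inversion
  expect_equal(ps$class, "INVERSION")
})

test_that("composite positives are distinguished from single-variant positives", {
  expect_true(single_variant_positive(c(inversion = 18, translocation = 8)))
  expect_false(single_variant_positive(c(a = 12, b = 8, c = 5)))
  expect_true(single_variant_positive(c(inversion = 15.0)))  # inclusive
  expect_false(single_variant_positive(numeric(0)))
})

test_that("CNG categorization picks the highest class above threshold", {
  expect_equal(categorize_cng(c("4-6" = 0.16, "7-9" = 0.01)), "4-6")
  expect_equal(categorize_cng(numeric(0)), "<=3")
  expect_equal(categorize_cng(c("4-6" = 0.05, "7-9" = 0.05)), "<=3")
  # threshold sensitivity
  fr <- c("4-6" = 0.17, "10+" = 0.08)
  expect_equal(categorize_cng(fr, theta = 0.05), "10+")
  expect_equal(categorize_cng(fr, theta = 0.10), "4-6")
  # brute force over all classes and a theta grid
  for (theta in c(0.02, 0.1, 0.2)) {
    fr <- c("4-6" = 0.12, "7-9" = 0.06, "10+" = 0.03)
    elevated <- names(fr)[fr >= theta]
    want <- if (length(elevated) == 0) "<=3" else
      elevated[which.max(match(elevated, cng_categories()))]
    expect_equal(categorize_cng(fr, theta = theta), want)
  }
  expect_error(categorize_cng(c("4-6" = -0.1)), "negative")
  expect_error(categorize_cng(c("5-7" = 0.2)), "unknown CNG")
})

test_that("sample summary integrates scoring, patterns and CNG", {
  # inversion-positive sample with sectioning fragments and modest CNG
  res <- summarize_counts(c("O+G;O+B;G+B" = 30, "O+G;O+B" = 6,
                            "O+G;O+G;O+G;O+G;O+G" = 16))
  expect_equal(res$status, "POSITIVE")
  expect_equal(res$n_rearranged, 36)
  expect_equal(res$pattern_set$class, "INVERSION")
  expect_false(res$composite_positive)
  expect_equal(res$cng_category, "4-6")
  expect_equal(unname(res$cng_fractions[["4-6"]]), 0.16)

  # composite positive: three variants each below 15%
  res <- summarize_counts(c("O+G;O" = 12, "O+G;O;G+B" = 8,
                            "O+G;O+B;G+B" = 5))
  expect_equal(res$status, "POSITIVE")
  expect_true(res$composite_positive)
  expect_equal(res$pattern_set$class,
               c("FIVE_PRIME_DELETION", "TRANSLOCATION", "INVERSION"))

  # atypical 3'-deletion-dominated sample: guideline-negative
  res <- summarize_counts(c("O+G;G+B;B" = 28, "O+G;G+B" = 32,
                            "O+G;G+B;G+B;B" = 14, "O+G;O+B;G+B" = 4))
  expect_equal(res$status, "NEGATIVE")
  expect_equal(res$percent_rearranged, 4)
  expect_true(res$atypical_flag)
  expect_equal(nrow(res$pattern_set), 0)
})

test_that("every reference combination is reachable and no folding combo is emitted", {
  ref <- pattern_reference()
  combos <- unique(ref[c("combination", "subthreshold")])
  for (i in seq_len(nrow(combos))) {
    nuc <- realize_pattern_sample(combos$combination[i],
                                  subthreshold = combos$subthreshold[i] == 1)
    res <- summarize_fish_sample(classify_nuclei(nuc))
    got <- vapply(res$pattern_set$class, function(cl) {
      switch(cl, INVERSION = "inversion", TRANSLOCATION = "translocation",
             FIVE_PRIME_DELETION = "five_prime_deletion",
             INTERSTITIAL_DELETION = "interstitial_deletion")
    }, character(1), USE.NAMES = FALSE)
    expect_equal(paste(got, collapse = "+"), combos$combination[i])
  }

  # an inversion-predominant sample with an interstitial minority folds:
  # [inversion, interstitial] is never emitted
  ps <- derive_pattern_set(c("O+B;G+B" = 60, "O+B" = 20))
  expect_equal(ps$class, "INVERSION")
})
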