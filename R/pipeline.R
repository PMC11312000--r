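#' Run the full concordance pipeline
#'
#' Classifies every nucleus, aggregates per-sample FISH results, joins the
#' IHC status from the case table, assigns the four-way concordance class
#' (insufficient samples are excluded from every denominator), and computes
#' the cohort summaries, the pattern-count contingency table with its
#' association statistics, and the CNG category table.
#'
#' @param nuclei Per-nucleus table (columns `sample_id`, `nucleus_id`,
#'   `tokens`, `split_ok`).
#' @param cases Case metadata (columns `case_id`, `ihc_status`); `case_id`
#'   matches `sample_id`.
#' @param theta_cng CNG reporting threshold.
#' @return Object of class `pipeline_report`: list with `per_case` (tibble),
#'   `counts` (named vector), `summaries` (see [cohort_summaries()]),
#'   `pattern_table`, `association` (or `NULL` when no positive samples in
#'   both groups), `cng_table`, `excluded` (case ids).
#' @export
run_pipeline <- function(nuclei, cases, theta_cng = 0.10) {
  stopifnot(all(c("sample_id", "tokens") %in% names(nuclei)),
            all(c("case_id", "ihc_status") %in% names(cases)))
  unknown <- setdiff(unique(nuclei$sample_id), cases$case_id)
  if (length(unknown) > 0L) {
    stop("nucleus table contains sample(s) without case metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cls <- classify_nuclei(nuclei)
  per_case <- lapply(split(cls, cls$sample_id), function(d) {
    r <- summarize_fish_sample(d, theta_cng = theta_cng)
    tibble::tibble(
      case_id = d$sample_id[1L],
      fish_status = r$status,
      percent_rearranged = r$percent_rearranged,
      n_enumerated = r$n_enumerated,
      pattern_set = paste(r$pattern_set$class, collapse = "+"),
      n_patterns = nrow(r$pattern_set),
      composite_positive = r$composite_positive,
      atypical_flag = r$atypical_flag,
      cng_category = r$cng_category)
  })
  per_case <- dplyr::bind_rows(per_case)
  per_case <- dplyr::left_join(per_case,
                               tibble::as_tibble(cases),
                               by = "case_id")
  per_case$concordance <- mapply(classify_concordance,
                                 per_case$ihc_status,
                                 per_case$fish_status)
  excluded <- per_case$case_id[per_case$concordance == "EXCLUDED"]
  kept <- per_case[per_case$concordance != "EXCLUDED", , drop = FALSE]

  counts <- c(
    pos_conc = sum(kept$concordance == "POS_CONC"),
    pos_disc = sum(kept$concordance == "POS_DISC"),
    neg_disc = sum(kept$concordance == "NEG_DISC"),
    neg_conc = sum(kept$concordance == "NEG_CONC"))

  pos <- kept[kept$fish_status == "POSITIVE" & kept$n_patterns > 0, ,
              drop = FALSE]
  pattern_table <- NULL
  association <- NULL
  if (nrow(pos) > 0L) {
    ps <- tibble::tibble(
      group = ifelse(pos$concordance == "POS_DISC", "discordant",
                     "concordant"),
      n_patterns = pos$n_patterns)
    pattern_table <- build_pattern_table(ps)
    if (all(rowSums(pattern_table) > 0)) {
      association <- association_test(pattern_table)
    }
  }

  cng_table <- table(factor(kept$concordance,
                            levels = c("POS_CONC", "POS_DISC",
                                       "NEG_DISC", "NEG_CONC")),
                     factor(kept$cng_category, levels = cng_categories()))

  structure(list(
    per_case = per_case,
    counts = counts,
    summaries = cohort_summaries(counts),
    pattern_table = pattern_table,
    association = association,
    cng_table = cng_table,
    excluded = excluded
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summaries
  cat("ALK concordance pipeline report\n")
  cat(sprintf("  %d cases analyzed (%d excluded as insufficient)\n",
              s$n, length(x$excluded)))
  cat(sprintf("  positive concordant %d | positive discordant %d | %s\n",
              x$counts[["pos_conc"]], x$counts[["pos_disc"]],
              sprintf("negative discordant %d | negative concordant %d",
                      x$counts[["neg_disc"]], x$counts[["neg_conc"]])))
  cat(sprintf("  discordance: %.2f%% overall (%.2f%% positive, %.2f%% negative)\n",
              s$overall_discordance, s$positive_discordance,
              s$negative_discordance))
  if (!is.na(s$pos_disc_of_fish_positive)) {
    cat(sprintf("  %.1f%% of FISH-positive cases are positive discordant\n",
                s$pos_disc_of_fish_positive))
  }
  cat(sprintf("  FISH sensitivity %.1f%%, specificity %.1f%%\n",
              s$sensitivity, s$specificity))
  if (!is.null(x$pattern_table)) {
    cat("  pattern-count table (rows: discordant, concordant; cols: 1-3):\n")
    print(x$pattern_table)
  }
  if (!is.null(x$association)) print(x$association)
  invisible(x)
}
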