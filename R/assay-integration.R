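#' IHC staining categories
#'
#' @return Character vector of recognised ALK (D5F3) staining categories.
#' @export
ihc_categories <- function() {
  c("none", "weak_1plus", "strong_2plus", "strong_3plus",
    "dot_like", "stippled")
}

#' Score an ALK immunohistochemistry observation
#'
#' Strong diffuse granular cytoplasmic staining (2+, 3+) is positive. In the
#' reevaluation stage the focal "dot-like" positivity is also labelled
#' positive. No staining, weak cytoplasmic staining (1+) and the stippled
#' pattern are negative.
#'
#' @param staining One of [ihc_categories()].
#' @param is_reevaluation Whether the observation comes from the repeated
#'   (reevaluation) IHC run; only then does dot-like staining score
#'   positive.
#' @return `"positive"` or `"negative"`.
#' @export
score_ihc <- function(staining, is_reevaluation = FALSE) {
  staining <- match.arg(staining, ihc_categories())
  pos <- staining %in% c("strong_2plus", "strong_3plus") ||
    (staining == "dot_like" && isTRUE(is_reevaluation))
  if (pos) "positive" else "negative"
}

#' Classify a case's IHC/FISH concordance
#'
#' @param ihc `"positive"` or `"negative"` protein expression.
#' @param fish FISH sample status; `"INSUFFICIENT"` propagates as an
#'   explicit `"EXCLUDED"` marker, never a concordance class.
#' @return One of `"POS_CONC"`, `"NEG_CONC"`, `"POS_DISC"` (FISH+, IHC-),
#'   `"NEG_DISC"` (FISH-, IHC+), or `"EXCLUDED"`.
#' @export
classify_concordance <- function(ihc, fish) {
  ihc <- match.arg(ihc, c("positive", "negative"))
  fish <- match.arg(fish, c("POSITIVE", "NEGATIVE", "INSUFFICIENT"))
  if (fish == "INSUFFICIENT") return("EXCLUDED")
  if (fish == "POSITIVE") {
    if (ihc == "positive") "POS_CONC" else "POS_DISC"
  } else {
    if (ihc == "positive") "NEG_DISC" else "NEG_CONC"
  }
}

#' Apply the IHC reevaluation step to cohort concordance counts
#'
#' Positive discordant cases (FISH+, IHC-) with sufficient material undergo
#' a repeated IHC in which dot-like positivity counts as positive; those
#' repeats reclassify the case as positive concordant. Total case count is
#' conserved.
#'
#' @param counts Named numeric vector or list with `pos_conc`, `pos_disc`,
#'   `neg_disc`, `neg_conc`.
#' @param n_repeated Number of positive discordant cases with a repeated
#'   IHC; must not exceed `counts$pos_disc`.
#' @param n_dot_like Number of repeats showing dot-like positivity; must not
#'   exceed `n_repeated`.
#' @return Updated counts (named numeric vector).
#' @export
#' @examples
#' apply_reevaluation(c(pos_conc = 184, pos_disc = 38,
#'                      neg_disc = 17, neg_conc = 2444), 9, 5)
apply_reevaluation <- function(counts, n_repeated, n_dot_like) {
  counts <- unlist(counts)
  need <- c("pos_conc", "pos_disc", "neg_disc", "neg_conc")
  stopifnot(all(need %in% names(counts)))
  if (n_repeated > counts[["pos_disc"]]) {
    stop("repeat IHC recorded for more cases than are positive discordant",
         call. = FALSE)
  }
  if (n_dot_like > n_repeated) {
    stop("more dot-like repeats than repeated cases", call. = FALSE)
  }
  counts[["pos_disc"]] <- counts[["pos_disc"]] - n_dot_like
  counts[["pos_conc"]] <- counts[["pos_conc"]] + n_dot_like
  counts[need]
}

#' Quality-control gate for an NGS sample
#'
#' Thresholds for the DNA+RNA panel workflow: at least 80 ng DNA
#' (inclusive), RNA concentration above 10 ng/uL, DV200 above 30% (DV200
#' below that signifies RNA degradation), library concentration above
#' 3 ng/uL, and tumor content above 20%. The first violated criterion is
#' reported; a missing field fails as `missing_data`.
#'
#' @param dna_ng DNA input mass in ng.
#' @param rna_conc RNA concentration in ng/uL.
#' @param dv200 Percentage of RNA fragments longer than 200 bp.
#' @param library_conc Library concentration in ng/uL.
#' @param tumor_content Tumor cell fraction in `[0, 1]`.
#' @return List with `pass` (logical) and `reason` (`NA` when passing).
#' @export
ngs_qc <- function(dna_ng, rna_conc, dv200, library_conc, tumor_content) {
  checks <- list(
    dna_insufficient = function() dna_ng >= 80,
    rna_insufficient = function() rna_conc > 10,
    rna_degraded = function() dv200 > 30,
    library_low = function() library_conc > 3,
    low_tumor_content = function() tumor_content > 0.20
  )
  for (reason in names(checks)) {
    ok <- checks[[reason]]()
    if (length(ok) != 1L || is.na(ok)) {
      return(list(pass = FALSE, reason = "missing_data"))
    }
    if (!ok) return(list(pass = FALSE, reason = reason))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Call gene fusions from unique supporting reads
#'
#' A fusion is called with high confidence when it is supported by at least
#' `min_unique_reads` unique reads (default 5).
#'
#' @param fusion_evidence Data frame with columns `partner_gene` and
#'   `unique_reads`.
#' @param min_unique_reads Minimum unique supporting reads.
#' @return Tibble of called fusions with an `alk_fusion` flag (here all
#'   evidence rows are ALK-partner candidates).
#' @export
call_ngs_fusion <- function(fusion_evidence, min_unique_reads = 5) {
  stopifnot(all(c("partner_gene", "unique_reads") %in%
                  names(fusion_evidence)))
  stopifnot(all(fusion_evidence$unique_reads >= 0))
  out <- tibble::as_tibble(fusion_evidence)
  out <- out[out$unique_reads >= min_unique_reads, , drop = FALSE]
  out$alk_fusion <- TRUE
  out
}

#' Sensitivity and specificity of FISH against protein expression
#'
#' Sensitivity is the number of positive concordant cases over positive
#' concordant plus FISH-negative discordant cases; specificity is negative
#' concordant over negative concordant plus FISH-positive discordant cases
#' (the standard form with IHC as reference). Both are returned as
#' percentages; a zero denominator yields `NA` with an explicit marker.
#'
#' @param pos_conc,pos_disc,neg_disc,neg_conc Non-negative case counts.
#' @return List with `sensitivity`, `specificity` (percent) and `undefined`
#'   (character vector naming any metric with a zero denominator).
#' @export
#' @examples
#' sensitivity_specificity(189, 33, 17, 2444)
sensitivity_specificity <- function(pos_conc, pos_disc, neg_disc, neg_conc) {
  stopifnot(pos_conc >= 0, pos_disc >= 0, neg_disc >= 0, neg_conc >= 0)
  undefined <- character(0)
  if (pos_conc + neg_disc > 0) {
    sens <- 100 * pos_conc / (pos_conc + neg_disc)
  } else {
    sens <- NA_real_; undefined <- c(undefined, "sensitivity")
  }
  if (neg_conc + pos_disc > 0) {
    spec <- 100 * neg_conc / (neg_conc + pos_disc)
  } else {
    spec <- NA_real_; undefined <- c(undefined, "specificity")
  }
  list(sensitivity = sens, specificity = spec, undefined = undefined)
}

#' Cohort-level concordance and discordance summaries
#'
#' @param counts Named vector/list with `pos_conc`, `pos_disc`, `neg_disc`,
#'   `neg_conc` (cases with both assays evaluable).
#' @return List with the total, the discordance rates (percent of all
#'   cases), the share of FISH-positive cases that are positive discordant,
#'   the share of FISH-negative cases that are negative discordant, and
#'   sensitivity/specificity.
#' @export
#' @examples
#' cohort_summaries(c(pos_conc = 189, pos_disc = 33,
#'                    neg_disc = 17, neg_conc = 2444))
cohort_summaries <- function(counts) {
  counts <- unlist(counts)
  need <- c("pos_conc", "pos_disc", "neg_disc", "neg_conc")
  stopifnot(all(need %in% names(counts)))
  pc <- counts[["pos_conc"]]; pd <- counts[["pos_disc"]]
  nd <- counts[["neg_disc"]]; nc <- counts[["neg_conc"]]
  n <- pc + pd + nd + nc
  if (n == 0) {
    return(list(n = 0, overall_discordance = NA_real_,
                positive_discordance = NA_real_,
                negative_discordance = NA_real_,
                pos_disc_of_fish_positive = NA_real_,
                neg_disc_of_fish_negative = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_))
  }
  ss <- sensitivity_specificity(pc, pd, nd, nc)
  list(
    n = n,
    overall_discordance = 100 * (pd + nd) / n,
    positive_discordance = 100 * pd / n,
    negative_discordance = 100 * nd / n,
    pos_disc_of_fish_positive = if (pc + pd > 0) 100 * pd / (pc + pd)
                                else NA_real_,
    neg_disc_of_fish_negative = if (nc + nd > 0) 100 * nd / (nc + nd)
                                else NA_real_,
    sensitivity = ss$sensitivity,
    specificity = ss$specificity
  )
}

#' ALK rearrangement frequency by stratum
#'
#' Tabulates FISH-positivity frequency over strata of a case table, e.g. by
#' sex and age decade.
#'
#' @param cases Data frame with a `fish_status` column (`"POSITIVE"` /
#'   `"NEGATIVE"`) and the stratification columns.
#' @param ... Stratification columns (tidy-select, e.g. `sex`).
#' @return Tibble with `n`, `n_positive` and `frequency` (percent) per
#'   stratum.
#' @export
alk_frequency_by <- function(cases, ...) {
  stopifnot("fish_status" %in% names(cases))
  cases |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_positive = sum(.data$fish_status == "POSITIVE"),
      frequency = 100 * sum(.data$fish_status == "POSITIVE") / dplyr::n(),
      .groups = "drop")
}

#' Call copy-number amplifications against per-gene thresholds
#'
#' Amplification calling is parameterized by a per-gene copy-count
#' threshold table with one documented anchor: 14 copies at 20% tumor
#' purity. No purity-scaling formula is assumed — at any other tumor
#' content an explicit threshold table must be supplied.
#'
#' @param cnv_evidence Data frame with columns `gene` and `copy_count`.
#' @param tumor_content Tumor cell fraction of the sample.
#' @param thresholds Named numeric vector of per-gene amplification
#'   thresholds (copies); the default applies only at 20% tumor content.
#' @return Tibble of evidence rows with an `amplified` flag; genes without
#'   a threshold get `NA`.
#' @export
call_ngs_cnv <- function(cnv_evidence, tumor_content = 0.20,
                         thresholds = c(ALK = 14)) {
  stopifnot(all(c("gene", "copy_count") %in% names(cnv_evidence)))
  if (missing(thresholds) && abs(tumor_content - 0.20) > 1e-9) {
    stop("the default threshold table is anchored at 20% tumor content; ",
         "supply explicit per-gene thresholds for other purities",
         call. = FALSE)
  }
  out <- tibble::as_tibble(cnv_evidence)
  thr <- unname(thresholds[out$gene])
  out$amplified <- ifelse(is.na(thr), NA, out$copy_count >= thr)
  out
}
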