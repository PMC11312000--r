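#' Copy-number-gain category labels, lowest to highest
#'
#' @return Character vector `c("<=3", "4-6", "7-9", "10+")`.
#' @export
cng_categories <- function() c("<=3", "4-6", "7-9", "10+")

#' Score a sample from its per-nucleus pattern calls
#'
#' Applies the guideline positivity rule: a sample is positive when at least
#' 15% of enumerated nuclei carry a rearrangement that counts toward
#' positivity (translocation, inversion, 5' deletion, interstitial
#' deletion). 3' deletion and unclassified nuclei never enter the positive
#' numerator; their presence raises the atypical flag. Fewer than
#' `min_cells` enumerable nuclei makes the sample insufficient, excluding it
#' from cohort statistics.
#'
#' @param calls Character vector of per-nucleus classes (one per enumerated
#'   nucleus), from [pattern_classes()].
#' @param cutoff Positivity cut-off as a fraction of enumerated nuclei
#'   (default 0.15, inclusive).
#' @param min_cells Minimum enumerable nuclei (default 50).
#' @return List with `status` (`"POSITIVE"`, `"NEGATIVE"`,
#'   `"INSUFFICIENT"`), `n_enumerated`, `n_rearranged`, `percent_rearranged`
#'   and `atypical_flag`.
#' @export
#' @examples
#' score_sample(c(rep("INVERSION", 26), rep("NOT_REARRANGED", 74)))$status
score_sample <- function(calls, cutoff = 0.15, min_cells = 50) {
  stopifnot(length(calls) > 0L)
  bad <- setdiff(unique(calls), pattern_classes())
  if (length(bad) > 0L) {
    stop("unknown pattern class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(calls)
  n_rearr <- sum(calls %in% rearrangement_classes())
  pct <- 100 * n_rearr / n
  status <- if (n < min_cells) {
    "INSUFFICIENT"
  } else if (pct >= 100 * cutoff) {
    "POSITIVE"
  } else {
    "NEGATIVE"
  }
  list(status = status,
       n_enumerated = n,
       n_rearranged = n_rearr,
       percent_rearranged = pct,
       atypical_flag = any(calls %in% c("THREE_PRIME_DELETION",
                                        "UNCLASSIFIED")))
}

#' Can a minority residue be derived from the predominant by sectioning?
#'
#' Tissue sectioning slices nuclei, so whole signal tokens can be lost from
#' a configuration but a co-localized token can never lose a single channel.
#' A minority residue is therefore derivable from the predominant — and
#' discounted as a sectioning artifact rather than a secondary pattern —
#' exactly when it is a sub-multiset of the predominant residue under exact
#' token equality.
#'
#' @param minority,predominant Character vectors of canonical tokens.
#' @return `TRUE` iff `minority` is a whole-token sub-multiset of
#'   `predominant`.
#' @export
#' @examples
#' derivable(c("O+B"), c("O+B", "G+B"))        # TRUE: folds into inversion
#' derivable(c("O+B", "G+B"), c("O+B"))        # FALSE: more complex
derivable <- function(minority, predominant) {
  if (length(minority) == 0L) return(TRUE)
  cnt_min <- table(minority)
  cnt_pred <- table(predominant)
  all(vapply(names(cnt_min), function(tok) {
    !is.na(cnt_pred[tok]) && cnt_min[[tok]] <= cnt_pred[[tok]]
  }, logical(1)))
}

#' Derive the ordered pattern set of a positive sample
#'
#' Implements the predominant/secondary pattern rule. The predominant
#' variant is the signal configuration with the highest percentage of
#' rearranged nuclei (ties broken toward the residue with more tokens, then
#' lexicographically by label; ties are recorded in the result attributes).
#' Every other variant is kept as a secondary/tertiary pattern only if it
#' reaches at least `minority_cutoff` percent of rearranged nuclei *and*
#' cannot be derived from the predominant configuration by whole-token loss
#' ([derivable()]); derivable variants are folded into the predominant's
#' class as sectioning artifacts, and non-derivable variants below the
#' cut-off are dropped. Surviving variants are grouped by pattern class and
#' ordered by summed percentage, predominant class first in its percentage
#' rank; at most `max_classes` classes are reported (overflow is recorded,
#' never silently lost).
#'
#' @param variant_pct Named numeric vector: residue multiset key (as in
#'   [signature_table()]) to percentage of rearranged nuclei. Only residues
#'   whose class counts toward positivity participate; others are ignored.
#' @param table Variant signature table.
#' @param minority_cutoff Minimum percentage of rearranged nuclei for a
#'   minority variant to survive (default 4).
#' @param max_classes Maximum number of reported classes (default 3).
#' @return Tibble with columns `class` and `percent`, ordered predominant
#'   first; attributes `predominant_variant`, `folded` (residue keys folded
#'   as artifacts), `dropped` (below-cut-off keys), `overflow` (classes
#'   beyond `max_classes`) and `ties` (logical).
#' @export
derive_pattern_set <- function(variant_pct, table = signature_table(),
                               minority_cutoff = 4, max_classes = 3) {
  empty <- tibble::tibble(class = character(0), percent = numeric(0))
  if (length(variant_pct) == 0L) return(empty)
  stopifnot(!is.null(names(variant_pct)), all(variant_pct >= 0))
  cls <- table$class[match(names(variant_pct), table$residue)]
  keep <- !is.na(cls) & cls %in% rearrangement_classes() & variant_pct > 0
  variant_pct <- variant_pct[keep]
  cls <- cls[keep]
  if (length(variant_pct) == 0L) return(empty)

  keys <- names(variant_pct)
  toks <- strsplit(keys, ";", fixed = TRUE)
  ntok <- lengths(toks)
  labels <- table$label[match(keys, table$residue)]
  ord <- order(-variant_pct, -ntok, labels, method = "radix")
  pred_i <- ord[1L]
  tied <- sum(variant_pct == variant_pct[pred_i]) > 1L
  pred_tokens <- toks[[pred_i]]
  pred_class <- cls[pred_i]

  class_pct <- stats::setNames(0, pred_class)
  class_pct[pred_class] <- variant_pct[pred_i]
  folded <- character(0)
  dropped <- character(0)
  for (i in seq_along(keys)) {
    if (i == pred_i) next
    if (derivable(toks[[i]], pred_tokens)) {
      # sectioning artifact of the predominant configuration
      class_pct[pred_class] <- class_pct[pred_class] + variant_pct[i]
      folded <- c(folded, keys[i])
    } else if (variant_pct[i] >= minority_cutoff) {
      ci <- cls[i]
      class_pct[ci] <- sum(class_pct[ci], variant_pct[i], na.rm = TRUE)
    } else {
      dropped <- c(dropped, keys[i])
    }
  }
  # order classes by percentage, predominant winning its percentage ties
  cl <- names(class_pct)
  pr <- unname(class_pct)
  o <- order(-pr, cl != pred_class, cl, method = "radix")
  cl <- cl[o]; pr <- pr[o]
  overflow <- character(0)
  if (length(cl) > max_classes) {
    overflow <- cl[-seq_len(max_classes)]
    pr <- pr[seq_len(max_classes)]
    cl <- cl[seq_len(max_classes)]
  }
  out <- tibble::tibble(class = cl, percent = pr)
  attr(out, "predominant_variant") <- keys[pred_i]
  attr(out, "folded") <- folded
  attr(out, "dropped") <- dropped
  attr(out, "overflow") <- overflow
  attr(out, "ties") <- tied
  out
}

#' Did any single variant reach the positivity cut-off on its own?
#'
#' A positive sample is either carried by one signal configuration at or
#' above 15% of enumerated nuclei, or it is a "composite positive" whose
#' total rearranged fraction crosses the cut-off through several variants
#' each below 15%.
#'
#' @param variant_pct_enumerated Named numeric vector: residue key to
#'   percentage of *enumerated* nuclei.
#' @param cutoff Percentage cut-off (default 15, inclusive).
#' @return `TRUE` if some single variant reaches the cut-off; `FALSE` marks
#'   a composite positive.
#' @export
single_variant_positive <- function(variant_pct_enumerated, cutoff = 15) {
  length(variant_pct_enumerated) > 0L &&
    any(variant_pct_enumerated >= cutoff)
}

#' Reduce a per-nucleus copy-number distribution to one CNG category
#'
#' Copy number gain is read from the break-apart probe as nuclei with
#' multiple intact fusion signals. A sample's category is the highest
#' copy-number class whose nucleus fraction reaches the reporting threshold
#' `theta`; if no elevated class does, the sample is "<=3".
#'
#' @param cng_fractions Named numeric vector of nucleus fractions (in
#'   `[0, 1]`) for the elevated classes `"4-6"`, `"7-9"`, `"10+"` (a
#'   `"<=3"` entry is allowed and ignored). Fractions must be non-negative
#'   and sum to at most 1.
#' @param theta Reporting threshold as a nucleus fraction (default 0.10).
#' @return One of [cng_categories()].
#' @export
#' @examples
#' categorize_cng(c("4-6" = 0.16, "7-9" = 0.01)) # "4-6"
categorize_cng <- function(cng_fractions, theta = 0.10) {
  if (length(cng_fractions) == 0L) return("<=3")
  stopifnot(!is.null(names(cng_fractions)))
  bad <- setdiff(names(cng_fractions), cng_categories())
  if (length(bad) > 0L) {
    stop("unknown CNG class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(cng_fractions < 0)) {
    stop("negative CNG fraction", call. = FALSE)
  }
  if (sum(cng_fractions) > 1 + 1e-9) {
    stop("CNG fractions sum to more than 1", call. = FALSE)
  }
  for (cat in rev(setdiff(cng_categories(), "<=3"))) {
    f <- cng_fractions[cat]
    if (!is.na(f) && f >= theta) return(cat)
  }
  "<=3"
}

# Per-nucleus copy number -> CNG class label.
cng_class_of_copies <- function(copy_number) {
  cut(copy_number, breaks = c(-Inf, 3, 6, 9, Inf),
      labels = cng_categories())
}

#' Summarize classified nuclei into a sample-level FISH result
#'
#' Aggregates the per-nucleus classes of one sample into the full
#' sample-level result: positivity status under the 15%/50-cell rule,
#' per-variant percentages, the ordered pattern set with sectioning-artifact
#' folding, composite-positive annotation, the atypical flag, and the
#' copy-number-gain profile and category.
#'
#' @param classified Data frame of classified nuclei for *one* sample, as
#'   produced by [classify_nuclei()] (columns `class`, `residue`,
#'   `copy_number`).
#' @param theta_cng CNG reporting threshold, see [categorize_cng()].
#' @param cutoff,min_cells Passed to [score_sample()].
#' @return Object of class `fish_sample_result`: a list with fields
#'   `status`, `n_enumerated`, `n_rearranged`, `percent_rearranged`,
#'   `variant_percentages` (of enumerated nuclei), `pattern_set` (tibble,
#'   empty unless positive), `composite_positive`, `atypical_flag`,
#'   `cng_fractions` and `cng_category`.
#' @export
summarize_fish_sample <- function(classified, theta_cng = 0.10,
                                  cutoff = 0.15, min_cells = 50) {
  stopifnot(all(c("class", "residue", "copy_number") %in% names(classified)))
  sc <- score_sample(classified$class, cutoff = cutoff,
                     min_cells = min_cells)
  rearr <- classified$class %in% rearrangement_classes()
  variant_counts <- table(classified$residue[rearr])
  variant_pct_enum <- 100 * as.numeric(variant_counts) / sc$n_enumerated
  names(variant_pct_enum) <- names(variant_counts)

  if (sc$status == "POSITIVE") {
    variant_pct_rearr <- 100 * as.numeric(variant_counts) / sc$n_rearranged
    names(variant_pct_rearr) <- names(variant_counts)
    pattern_set <- derive_pattern_set(variant_pct_rearr)
    composite <- !single_variant_positive(variant_pct_enum,
                                          cutoff = 100 * cutoff)
  } else {
    pattern_set <- tibble::tibble(class = character(0),
                                  percent = numeric(0))
    composite <- NA
  }

  cng_tab <- table(cng_class_of_copies(classified$copy_number))
  cng_fractions <- as.numeric(cng_tab) / sc$n_enumerated
  names(cng_fractions) <- names(cng_tab)

  structure(list(
    status = sc$status,
    n_enumerated = sc$n_enumerated,
    n_rearranged = sc$n_rearranged,
    percent_rearranged = sc$percent_rearranged,
    variant_percentages = variant_pct_enum,
    pattern_set = pattern_set,
    composite_positive = composite,
    atypical_flag = sc$atypical_flag,
    cng_fractions = cng_fractions,
    cng_category = categorize_cng(
      cng_fractions[setdiff(names(cng_fractions), "<=3")],
      theta = theta_cng)
  ), class = "fish_sample_result")
}

#' @export
print.fish_sample_result <- function(x, ...) {
  cat("FISH sample result:", x$status,
      sprintf("(%d/%d nuclei rearranged, %.1f%%)\n",
              x$n_rearranged, x$n_enumerated, x$percent_rearranged))
  if (nrow(x$pattern_set) > 0L) {
    cat("  pattern set:",
        paste(sprintf("%s (%.1f%% of rearranged)", x$pattern_set$class,
                      x$pattern_set$percent), collapse = " + "), "\n")
    if (isTRUE(x$composite_positive)) {
      cat("  composite positive: no single variant reached the cut-off\n")
    }
  }
  if (isTRUE(x$atypical_flag)) {
    cat("  atypical: 3' deletion and/or unclassified configurations present\n")
  }
  cat("  CNG category:", x$cng_category, "\n")
  invisible(x)
}
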