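#' Representative residue configuration for each pattern class
#'
#' The generator renders a rearranged nucleus as intact fusion tokens plus
#' the residue of its variant; these are the canonical single-variant
#' representatives used when a pattern class must be realized.
#'
#' @return Named list of canonical token vectors.
#' @export
class_representatives <- function() {
  list(
    INVERSION = c("O+B", "G+B"),
    TRANSLOCATION = c("O", "G+B"),
    FIVE_PRIME_DELETION = "O",
    INTERSTITIAL_DELETION = "O+B"
  )
}

# Case archetype names.
archetypes <- function() {
  c("pos_concordant", "pos_discordant", "neg_concordant", "neg_discordant")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions of the reference cohort: the
#' FISH-positive archetypes draw a pattern combination per sample from the
#' observed combination frequencies (see [pattern_reference()]), the
#' rearranged fraction is Beta-distributed with archetype-specific means,
#' the sectioning-artifact process deletes one whole token per affected
#' nucleus, and CNG categories follow the observed per-group frequencies
#' with a 20% elevated-nucleus fraction (above the 10% reporting
#' threshold).
#'
#' @param n_cases Named integer vector: cases per archetype
#'   (`pos_concordant`, `pos_discordant`, `neg_concordant`,
#'   `neg_discordant`).
#' @param nuclei_per_sample Nuclei enumerated per sample (default 100).
#' @param p_artifact Probability that a nucleus suffers a sectioning event
#'   deleting one whole token uniformly at random (default 0.10).
#' @param rearranged_mean Named numeric vector: mean rearranged fraction per
#'   archetype.
#' @param beta_concentration Concentration (alpha + beta) of the Beta
#'   distribution of the per-sample rearranged fraction; a scalar or a
#'   named per-archetype vector. The FISH-negative archetypes default to a
#'   much tighter distribution: a negative case is one whose true
#'   rearranged fraction sits well below the clinical cut-off, with only
#'   background-level split signals.
#' @param elevated_fraction Fraction of nuclei carrying the elevated copy
#'   number in samples with an elevated CNG category.
#' @param seed Global seed; per-case streams are split from it
#'   deterministically so cohorts are stable under case-count changes.
#' @return Object of class `cohort_config` (a list).
#' @export
cohort_config <- function(n_cases = c(pos_concordant = 168,
                                      pos_discordant = 29,
                                      neg_concordant = 100,
                                      neg_discordant = 5),
                          nuclei_per_sample = 100,
                          p_artifact = 0.10,
                          rearranged_mean = c(pos_concordant = 0.45,
                                              pos_discordant = 0.30,
                                              neg_concordant = 0.03,
                                              neg_discordant = 0.03),
                          beta_concentration = c(pos_concordant = 40,
                                                 pos_discordant = 40,
                                                 neg_concordant = 250,
                                                 neg_discordant = 250),
                          elevated_fraction = 0.20,
                          seed = 1L) {
  stopifnot(all(archetypes() %in% names(n_cases)),
            all(n_cases >= 0),
            nuclei_per_sample >= 1,
            p_artifact >= 0, p_artifact <= 1,
            all(archetypes() %in% names(rearranged_mean)),
            all(rearranged_mean > 0), all(rearranged_mean < 1),
            all(beta_concentration > 0),
            elevated_fraction > 0, elevated_fraction <= 1)
  if (length(beta_concentration) == 1L) {
    beta_concentration <- stats::setNames(
      rep(beta_concentration, 4), archetypes())
  }
  stopifnot(all(archetypes() %in% names(beta_concentration)))
  structure(list(
    n_cases = n_cases,
    nuclei_per_sample = nuclei_per_sample,
    p_artifact = p_artifact,
    rearranged_mean = rearranged_mean,
    beta_concentration = beta_concentration,
    elevated_fraction = elevated_fraction,
    combo_freq = combo_frequencies(),
    cng_freq = cng_frequencies(),
    ihc_profile = list(
      pos_concordant = "strong_3plus",
      pos_discordant = "none",
      neg_concordant = "none",
      neg_discordant = "strong_2plus"),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Per-sample pattern-combination frequencies for the FISH-positive
# archetypes, taken from the shipped pattern-distribution reference.
combo_frequencies <- function() {
  ref <- pattern_reference()
  split(ref[c("combination", "subthreshold", "n_samples")], ref$group)
}

# Per-sample CNG-category frequencies per archetype, from the shipped CNG
# reference (FISH-negative concordant cases are not in the reference;
# baseline diploid is used).
cng_frequencies <- function() {
  ref <- cng_reference()
  out <- lapply(split(ref, ref$group), function(d) {
    stats::setNames(d$n_cases / sum(d$n_cases), d$cng_category)
  })
  list(pos_concordant = out$positive_concordant,
       pos_discordant = out$positive_discordant,
       neg_discordant = out$negative_discordant,
       neg_concordant = stats::setNames(c(1, 0, 0, 0), cng_categories()))
}

# Deterministic per-case seed splitting: a simple LCG-style mix of the
# global seed and the case counter, stable under case-count changes.
case_seed <- function(seed, counter) {
  as.integer((1103515245 * (as.double(seed) %% 65536) +
                12345 * as.double(counter)) %% 2147483647)
}

# Representative intact-copy count per CNG category.
copies_for_category <- function(category) {
  switch(category, "<=3" = 2L, "4-6" = 5L, "7-9" = 8L, "10+" = 11L)
}

# Token-string renderer for one nucleus.
render_nucleus <- function(residue_tokens, n_intact) {
  paste(c(rep("O+G", n_intact), residue_tokens), collapse = ";")
}

# Variant mixture (residue key -> probability) realizing an ordered pattern
# combination; the predominant class receives the largest share.
mixture_for_combo <- function(classes) {
  reps <- class_representatives()
  stopifnot(all(classes %in% names(reps)))
  w <- switch(length(classes), c(1), c(0.7, 0.3), c(0.5, 0.3, 0.2))
  keys <- vapply(reps[classes], residue_key, character(1))
  stats::setNames(w, keys)
}

#' Generate one synthetic case
#'
#' Draws a case of the given archetype: a pattern combination (for
#' FISH-positive archetypes), a Beta-distributed rearranged fraction, a CNG
#' category, then renders each nucleus as intact fusion tokens plus the
#' residue of its drawn variant. With probability `p_artifact` a nucleus
#' suffers a sectioning event deleting one whole token uniformly at random,
#' producing the degraded minority variants the derivation rule folds back.
#'
#' @param config A [cohort_config()].
#' @param archetype One of `"pos_concordant"`, `"pos_discordant"`,
#'   `"neg_concordant"`, `"neg_discordant"`.
#' @param case_counter Integer counter identifying the case within the
#'   cohort (drives seed splitting).
#' @return List with `nuclei` (tibble: `sample_id`, `nucleus_id`, `tokens`,
#'   `split_ok`), `case` (one-row tibble of metadata) and `truth` (list:
#'   true pattern classes, rearranged fraction, CNG category, mixture).
#' @export
generate_case <- function(config, archetype, case_counter) {
  stopifnot(inherits(config, "cohort_config"))
  archetype <- match.arg(archetype, archetypes())
  sid <- sprintf("%s_%04d", archetype, case_counter)
  withr_seed <- case_seed(config$seed, case_counter)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)

  n <- config$nuclei_per_sample
  mu <- config$rearranged_mean[[archetype]]
  kappa <- config$beta_concentration[[archetype]]
  frac <- stats::rbeta(1, mu * kappa, (1 - mu) * kappa)
  n_rearr <- stats::rbinom(1, n, frac)

  # pattern combination and variant mixture
  if (archetype %in% c("pos_concordant", "pos_discordant")) {
    grp <- if (archetype == "pos_concordant") "concordant" else "discordant"
    cf <- config$combo_freq[[grp]]
    row <- cf[sample.int(nrow(cf), 1, prob = cf$n_samples), ]
    classes <- combo_classes(row$combination)
  } else {
    classes <- "INVERSION"
  }
  mixture <- mixture_for_combo(classes)

  # CNG category and per-nucleus copy numbers
  cngf <- config$cng_freq[[archetype]]
  cng_cat <- sample(names(cngf), 1, prob = cngf)
  elevated <- stats::runif(n) < config$elevated_fraction
  copies <- ifelse(cng_cat != "<=3" & elevated,
                   copies_for_category(cng_cat), 2L)

  rearranged <- seq_len(n) <= n_rearr
  variant <- character(n)
  variant[rearranged] <- sample(names(mixture), n_rearr, replace = TRUE,
                                prob = mixture)
  toks <- vector("list", n)
  for (i in seq_len(n)) {
    res <- if (rearranged[i]) {
      strsplit(variant[i], ";", fixed = TRUE)[[1]]
    } else character(0)
    n_intact <- max(copies[i] - as.integer(rearranged[i]), 0L)
    tk <- c(rep("O+G", n_intact), res)
    if (length(tk) > 0L && stats::runif(1) < config$p_artifact) {
      tk <- tk[-sample.int(length(tk), 1)]  # sectioning: lose one token
    }
    toks[[i]] <- tk
  }
  keep <- lengths(toks) > 0L  # fully sectioned-away nuclei are unenumerable
  nuclei <- tibble::tibble(
    sample_id = sid,
    nucleus_id = sprintf("n%03d", seq_len(n)[keep]),
    tokens = vapply(toks[keep], paste, character(1), collapse = ";"),
    split_ok = NA_integer_)

  ihc_staining <- config$ihc_profile[[archetype]]
  case <- tibble::tibble(
    case_id = sid,
    archetype = archetype,
    ihc_staining = ihc_staining,
    ihc_status = score_ihc(ihc_staining))
  truth <- list(classes = sort(unique(classes)),
                ordered_classes = classes,
                rearranged_fraction = frac,
                n_rearranged = n_rearr,
                cng_category = cng_cat,
                mixture = mixture)
  list(nuclei = nuclei, case = case, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Reproducible from `config$seed`: identical configuration and seed give
#' identical output. Per-case randomness is split deterministically from
#' the global seed, so adding cases does not perturb existing ones.
#'
#' @param config A [cohort_config()].
#' @return List with `nuclei` (tibble over all cases), `cases` (metadata
#'   tibble) and `truth` (tibble with list-columns of ground truth).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  counter <- 0L
  nuclei <- list(); cases <- list(); truths <- list()
  for (a in archetypes()) {
    for (i in seq_len(config$n_cases[[a]])) {
      counter <- counter + 1L
      g <- generate_case(config, a, counter)
      nuclei[[counter]] <- g$nuclei
      cases[[counter]] <- g$case
      truths[[counter]] <- tibble::tibble(
        case_id = g$case$case_id,
        archetype = a,
        true_classes = list(g$truth$classes),
        true_rearranged_fraction = g$truth$rearranged_fraction,
        true_n_rearranged = g$truth$n_rearranged,
        true_cng_category = g$truth$cng_category)
    }
  }
  if (counter == 0L) {
    return(list(
      nuclei = tibble::tibble(sample_id = character(0),
                              nucleus_id = character(0),
                              tokens = character(0),
                              split_ok = integer(0)),
      cases = tibble::tibble(case_id = character(0),
                             archetype = character(0),
                             ihc_staining = character(0),
                             ihc_status = character(0)),
      truth = tibble::tibble(case_id = character(0),
                             archetype = character(0),
                             true_classes = list(),
                             true_rearranged_fraction = numeric(0),
                             true_n_rearranged = integer(0),
                             true_cng_category = character(0))))
  }
  list(nuclei = dplyr::bind_rows(nuclei),
       cases = dplyr::bind_rows(cases),
       truth = dplyr::bind_rows(truths))
}

# Parse a combination label like "interstitial_deletion+inversion" into
# ordered class names.
combo_classes <- function(combination) {
  map <- c(inversion = "INVERSION",
           translocation = "TRANSLOCATION",
           five_prime_deletion = "FIVE_PRIME_DELETION",
           interstitial_deletion = "INTERSTITIAL_DELETION")
  parts <- strsplit(combination, "+", fixed = TRUE)[[1]]
  bad <- setdiff(parts, names(map))
  if (length(bad) > 0L) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[parts])
}

# Inverse of combo_classes.
combo_label <- function(classes) {
  map <- c(INVERSION = "inversion",
           TRANSLOCATION = "translocation",
           FIVE_PRIME_DELETION = "five_prime_deletion",
           INTERSTITIAL_DELETION = "interstitial_deletion")
  paste(unname(map[classes]), collapse = "+")
}

# Deterministic variant counts (nuclei out of n) realizing an ordered
# combination; subthreshold samples keep every variant below the 15%
# positivity cut-off while the total stays above it.
realization_counts <- function(classes, subthreshold, n_nuclei) {
  reps <- class_representatives()
  k <- length(classes)
  stopifnot(k >= 1L, k <= 3L)
  scale <- n_nuclei / 100
  if (!subthreshold) {
    base <- switch(k, c(40), c(30, 10), c(20, 10, 6))
    keys <- vapply(reps[classes], residue_key, character(1))
    counts <- stats::setNames(round(base * scale), keys)
    # exercise the artifact-folding rule: add a derivable sectioning
    # fragment of the predominant configuration when one exists
    pred <- reps[[classes[1L]]]
    if (length(pred) >= 2L) {
      frag_key <- residue_key(pred[-length(pred)])
      counts[frag_key] <- sum(counts[frag_key], round(6 * scale),
                              na.rm = TRUE)
    }
    counts
  } else if (k == 1L) {
    # composite positive carried by two signature variants of one class
    sig <- signature_table()
    vars <- sig$residue[sig$class == classes[1L]]
    stopifnot(length(vars) >= 2L)
    stats::setNames(round(c(10, 8) * scale), vars[1:2])
  } else {
    base <- switch(k - 1L, c(12, 9), c(12, 9, 5))
    keys <- vapply(reps[classes], residue_key, character(1))
    stats::setNames(round(base * scale), keys)
  }
}

#' Deterministically realize a sample with a prescribed pattern combination
#'
#' Builds a nucleus table whose classification and pattern-set derivation
#' yield exactly the requested ordered combination: the predominant class
#' receives the largest variant, secondary/tertiary classes smaller
#' non-derivable variants, and (for above-cut-off samples whose predominant
#' configuration has several tokens) a derivable sectioning fragment that
#' must fold back into the predominant class. Subthreshold samples are
#' composite positives: every variant stays below 15% of nuclei while the
#' total rearranged fraction crosses the cut-off.
#'
#' @param combination Label such as `"interstitial_deletion+inversion"`
#'   (predominant first).
#' @param subthreshold Logical: realize as a composite positive.
#' @param n_nuclei Nuclei per sample (default 100).
#' @param sample_id Sample identifier.
#' @param seed Optional seed controlling the (cosmetic) shuffling of
#'   nucleus order.
#' @return Tibble with `sample_id`, `nucleus_id`, `tokens`, `split_ok`.
#' @export
realize_pattern_sample <- function(combination, subthreshold = FALSE,
                                   n_nuclei = 100, sample_id = "s1",
                                   seed = NULL) {
  classes <- combo_classes(combination)
  counts <- realization_counts(classes, subthreshold, n_nuclei)
  stopifnot(sum(counts) <= n_nuclei)
  toks <- character(0)
  for (key in names(counts)) {
    res <- strsplit(key, ";", fixed = TRUE)[[1]]
    toks <- c(toks, rep(render_nucleus(res, 1L), counts[[key]]))
  }
  toks <- c(toks, rep("O+G;O+G", n_nuclei - length(toks)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    toks <- sample(toks)
  }
  tibble::tibble(sample_id = sample_id,
                 nucleus_id = sprintf("n%03d", seq_len(n_nuclei)),
                 tokens = toks,
                 split_ok = NA_integer_)
}

#' Simulate the pattern-distribution cohort and derive its pattern sets
#'
#' Expands a pattern-distribution reference (one row per combination x
#' cut-off stratum with a sample count) into one deterministic synthetic
#' sample per counted case, classifies every nucleus with the tri-color
#' rules and derives each sample's pattern set. This exercises the full
#' classification + derivation path on a cohort whose ground truth is
#' known.
#'
#' @param reference Tibble as returned by [pattern_reference()].
#' @param n_nuclei Nuclei per sample.
#' @param seed Seed for the per-sample nucleus shuffling.
#' @return Tibble with one row per sample: `sample_id`, `group`,
#'   `true_combination`, `subthreshold`, `status`, `composite_positive`,
#'   `pattern_set` (ordered `+`-joined class labels), `n_patterns`.
#' @export
simulate_pattern_cohort <- function(reference = pattern_reference(),
                                    n_nuclei = 100, seed = 1L) {
  stopifnot(all(c("group", "combination", "subthreshold", "n_samples")
                %in% names(reference)))
  rows <- reference[rep(seq_len(nrow(reference)), reference$n_samples), ]
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    sid <- sprintf("%s_%03d", substr(rows$group[i], 1, 4), i)
    nuc <- realize_pattern_sample(rows$combination[i],
                                  subthreshold = rows$subthreshold[i] == 1,
                                  n_nuclei = n_nuclei,
                                  sample_id = sid,
                                  seed = seed + i)
    cls <- classify_nuclei(nuc)
    res <- summarize_fish_sample(cls)
    out[[i]] <- tibble::tibble(
      sample_id = sid,
      group = rows$group[i],
      true_combination = rows$combination[i],
      subthreshold = rows$subthreshold[i] == 1,
      status = res$status,
      composite_positive = res$composite_positive,
      pattern_set = combo_label(res$pattern_set$class),
      n_patterns = nrow(res$pattern_set))
  }
  dplyr::bind_rows(out)
}
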