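# Delimited-text dialect for all tables: UTF-8, tab-separated, '#' comment
# lines, required headers. Chosen so fixtures stay diff-able.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("cannot read ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Read a per-nucleus signal table
#'
#' One row per nucleus with columns `sample_id`, `nucleus_id`, `tokens`
#' (semicolon-separated tokens, `+` for co-localization, e.g.
#' `"O+G;O+B;G+B"`) and `split_ok` (0/1/NA; the break-apart two-diameter
#' distance flag, measured upstream). Malformed rows (unknown channel
#' codes, empty token fields) are collected and reported with their line
#' numbers in a single error.
#'
#' @param path Path to a tab-separated file.
#' @return Validated tibble.
#' @export
read_nucleus_table <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "nucleus_id", "tokens",
                                "split_ok"))
  if (nrow(d) == 0L) stop("schema error in ", path, ": no data rows",
                          call. = FALSE)
  errs <- character(0)
  for (i in seq_len(nrow(d))) {
    msg <- tryCatch({
      tk <- parse_tokens(as.character(d$tokens[i]))
      if (length(tk) == 0L) "no signal tokens" else NA_character_
    }, error = function(e) conditionMessage(e))
    if (!is.na(msg)) errs <- c(errs, sprintf("row %d: %s", i, msg))
  }
  if (!all(is.na(d$split_ok) | d$split_ok %in% c(0, 1))) {
    errs <- c(errs, "split_ok must be 0, 1 or NA")
  }
  if (length(errs) > 0L) {
    stop("invalid nucleus table ", path, ":\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  d$tokens <- vapply(as.character(d$tokens), function(s) {
    paste(parse_tokens(s), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  d$split_ok <- as.integer(d$split_ok)
  d
}

#' Write a per-nucleus signal table
#'
#' @param nuclei Tibble as produced by [generate_cohort()] or
#'   [realize_pattern_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(nuclei, path) {
  stopifnot(all(c("sample_id", "nucleus_id", "tokens", "split_ok")
                %in% names(nuclei)))
  utils::write.table(nuclei, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a case metadata table
#'
#' One row per case; requires at least `case_id` and `ihc_status`
#' (`"positive"`/`"negative"`); further columns (age, sex, histology, NGS
#' fields) are passed through.
#'
#' @param path Path to a tab-separated file.
#' @return Tibble.
#' @export
read_case_table <- function(path) {
  d <- read_tsv_checked(path, c("case_id", "ihc_status"))
  bad <- !d$ihc_status %in% c("positive", "negative")
  if (any(bad)) {
    stop("invalid ihc_status in rows ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  d
}

# Path to a shipped reference table.
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "alkconcord")
  if (!nzchar(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}

#' Reference distribution of pattern combinations in FISH-positive samples
#'
#' Counts of samples per ordered pattern combination (predominant class
#' first), stratified by IHC concordance group and by whether any single
#' variant reached the 15% cut-off (`subthreshold = 1` marks composite
#' positives). 29 discordant and 168 concordant samples.
#'
#' @return Tibble with columns `group`, `combination`, `subthreshold`,
#'   `n_samples`.
#' @export
pattern_reference <- function() {
  read_tsv_checked(fixture_path("pattern_distribution.tsv"),
                   c("group", "combination", "subthreshold", "n_samples"))
}

#' Reference copy-number-gain category counts per concordance group
#'
#' @return Tibble with columns `group`, `cng_category`, `n_cases`.
#' @export
cng_reference <- function() {
  read_tsv_checked(fixture_path("cng_distribution.tsv"),
                   c("group", "cng_category", "n_cases"))
}

#' Reference cohort concordance counts
#'
#' Key/value pairs of the reference cohort's case counts: total analyzed,
#' initial and final concordance-class counts, and the IHC reevaluation
#' figures (repeated cases, dot-like reclassifications).
#'
#' @return Named numeric vector.
#' @export
cohort_counts_reference <- function() {
  d <- read_tsv_checked(fixture_path("cohort_counts.tsv"),
                        c("key", "value"))
  stats::setNames(as.numeric(d$value), d$key)
}

#' Reference discordant/concordant cases with NGS results
#'
#' Seventeen cases with FISH status, rearranged-nucleus percentage, derived
#' pattern combination, IHC status and the called ALK fusion partner (if
#' any); multi-component tumors are represented by their reported dominant
#' component.
#'
#' @return Tibble.
#' @export
ngs_case_reference <- function() {
  read_tsv_checked(fixture_path("ngs_cases.tsv"),
                   c("case_id", "sex", "age", "fish_status",
                     "percent_rearranged", "pattern", "ihc_status",
                     "alk_fusion_partner"))
}

#' Write sample-level FISH results as JSON
#'
#' Serializes one or more `fish_sample_result` objects, including the full
#' per-variant percentages, to a JSON report.
#'
#' @param results Named list of [summarize_fish_sample()] results (names
#'   are sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_json <- function(results, path) {
  stopifnot(is.list(results), !is.null(names(results)))
  payload <- lapply(results, function(r) {
    stopifnot(inherits(r, "fish_sample_result"))
    list(status = r$status,
         n_enumerated = r$n_enumerated,
         n_rearranged = r$n_rearranged,
         percent_rearranged = r$percent_rearranged,
         variant_percentages = as.list(r$variant_percentages),
         pattern_set = r$pattern_set,
         composite_positive = r$composite_positive,
         atypical_flag = r$atypical_flag,
         cng_fractions = as.list(r$cng_fractions),
         cng_category = r$cng_category)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
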