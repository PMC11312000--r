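#' Split a nucleus into its rearranged residue and copy number
#'
#' Removes all intact fusion tokens (co-localized O+G, with or without B)
#' from a nucleus; what remains is the rearranged residue matched against
#' the variant signature table. The number of intact fusion tokens removed
#' is the nucleus's ALK copy number.
#'
#' @param tokens Character vector of canonical tokens (see [parse_tokens()]);
#'   must be non-empty — a nucleus with no signals cannot be enumerated.
#' @return List with `residue` (sorted character vector) and `copy_number`
#'   (count of intact fusion tokens).
#' @export
#' @examples
#' extract_residue(parse_tokens("O+G;O+B;G+B"))
extract_residue <- function(tokens) {
  if (length(tokens) == 0L) {
    stop("unenumerable nucleus: no signal tokens", call. = FALSE)
  }
  intact <- is_intact_fusion(tokens)
  list(residue = sort_tokens(tokens[!intact]),
       copy_number = sum(intact))
}

#' Classify one nucleus observed with the tri-color ALK/EML4 fusion probe
#'
#' Extracts the rearranged residue and matches it by exact multiset equality
#' against the variant signature table. An empty residue is
#' `NOT_REARRANGED`; a non-empty residue absent from the table is
#' `UNCLASSIFIED` (the raw residue is preserved in the result so unusual
#' configurations are surfaced, never silently dropped).
#'
#' @param tokens Character vector of canonical tokens for one nucleus.
#' @param table Variant signature table, by default [signature_table()].
#' @return List with `class`, `residue` (multiset key), `label`, and
#'   `copy_number`.
#' @export
#' @examples
#' classify_nucleus_tricheck(parse_tokens("O+G;O+B;G+B"))$class # inversion
classify_nucleus_tricheck <- function(tokens, table = signature_table()) {
  r <- extract_residue(tokens)
  key <- residue_key(r$residue)
  if (length(r$residue) == 0L) {
    cls <- "NOT_REARRANGED"
  } else {
    hit <- match(key, table$residue)
    cls <- if (is.na(hit)) "UNCLASSIFIED" else table$class[hit]
  }
  list(class = cls, residue = key, label = residue_label(r$residue),
       copy_number = r$copy_number)
}

#' Classify one nucleus observed with the dual-color break-apart probe
#'
#' Guideline scoring for the break-apart probe: a nucleus is positive when
#' it shows two isolated signals (3' orange and 5' green) at least two
#' signal diameters apart, and/or a single isolated 3' orange signal without
#' an isolated green. An isolated orange/green pair below the distance
#' criterion is the equivocal "short break" pattern — counted as negative for
#' scoring but flagged for retesting with the tri-color probe.
#'
#' @param tokens Character vector of canonical tokens; only O/G channels are
#'   meaningful (use [drop_blue()] to re-encode tri-color observations).
#' @param split_distance_ok Logical flag: `TRUE` iff the isolated
#'   orange/green pair is separated by at least two signal diameters.
#'   Required (non-`NA`) only when both isolated signals are present.
#' @return One of `"POSITIVE"`, `"NEGATIVE"`, `"SHORT_BREAK"`.
#' @export
classify_nucleus_breakapart <- function(tokens, split_distance_ok = NA) {
  if (length(tokens) == 0L) {
    stop("unenumerable nucleus: no signal tokens", call. = FALSE)
  }
  has_o <- any(tokens == "O")
  has_g <- any(tokens == "G")
  if (has_o && has_g) {
    if (is.na(split_distance_ok)) {
      stop("split_distance_ok is required for an isolated orange/green pair",
           call. = FALSE)
    }
    if (split_distance_ok) "POSITIVE" else "SHORT_BREAK"
  } else if (has_o) {
    "POSITIVE"
  } else {
    "NEGATIVE"
  }
}

#' Classify a table of nuclei with the tri-color probe
#'
#' Vectorised wrapper around [classify_nucleus_tricheck()] for a nucleus
#' table (one row per nucleus). Identical token strings are classified once
#' and joined back, so large cohorts stay fast.
#'
#' @param nuclei Data frame with at least columns `sample_id`, `nucleus_id`,
#'   `tokens` (token-encoded string, see [parse_tokens()]).
#' @param table Variant signature table.
#' @return Tibble: the input columns plus `class`, `residue`, `label`,
#'   `copy_number`.
#' @export
classify_nuclei <- function(nuclei, table = signature_table()) {
  stopifnot(all(c("sample_id", "nucleus_id", "tokens") %in% names(nuclei)))
  uniq <- unique(nuclei$tokens)
  res <- lapply(uniq, function(s) {
    classify_nucleus_tricheck(parse_tokens(s), table = table)
  })
  idx <- match(nuclei$tokens, uniq)
  out <- tibble::as_tibble(nuclei)
  out$class <- vapply(res, `[[`, character(1), "class")[idx]
  out$residue <- vapply(res, `[[`, character(1), "residue")[idx]
  out$label <- vapply(res, `[[`, character(1), "label")[idx]
  out$copy_number <- vapply(res, `[[`, integer(1), "copy_number")[idx]
  out
}
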