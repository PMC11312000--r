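#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

# Fluorochrome channels of the tri-color ALK/EML4 fusion probe, in canonical
# order: O = 3' ALK arm (orange), G = 5' ALK arm (green), B = EML4 arm (blue).
# The dual-color break-apart probe carries only O and G.
.CHANNELS <- c("O", "G", "B")

#' Pattern classes recognised by the per-nucleus classifier
#'
#' Returns the vocabulary of rearrangement pattern classes. The first four
#' (translocation, inversion, 5' deletion, interstitial deletion) count
#' toward FISH positivity under scoring guidelines; 3' deletion and
#' unclassified configurations are recorded and flagged as atypical but never
#' contribute to the positive cell fraction.
#'
#' @return Character vector of class names.
#' @export
pattern_classes <- function() {
  c("TRANSLOCATION", "INVERSION", "FIVE_PRIME_DELETION",
    "INTERSTITIAL_DELETION", "THREE_PRIME_DELETION",
    "UNCLASSIFIED", "NOT_REARRANGED")
}

#' Pattern classes that count toward positivity
#'
#' @return Character vector: the classes whose nuclei enter the positive cell
#'   fraction under guideline scoring.
#' @export
rearrangement_classes <- function() {
  c("TRANSLOCATION", "INVERSION", "FIVE_PRIME_DELETION",
    "INTERSTITIAL_DELETION")
}

# Canonicalize a single token: channels sorted O, G, B; validates codes.
canonical_token <- function(token) {
  chs <- trimws(strsplit(token, "+", fixed = TRUE)[[1]])
  chs <- chs[nzchar(chs)]
  if (length(chs) == 0L) {
    stop("empty signal token", call. = FALSE)
  }
  bad <- setdiff(chs, .CHANNELS)
  if (length(bad) > 0L) {
    stop("unknown channel code(s): ", paste(bad, collapse = ", "),
         " (valid codes are O, G, B)", call. = FALSE)
  }
  if (anyDuplicated(chs)) {
    stop("duplicated channel within token: ", token, call. = FALSE)
  }
  paste(.CHANNELS[.CHANNELS %in% chs], collapse = "+")
}

#' Parse a token-encoded nucleus into canonical signal tokens
#'
#' A nucleus is encoded as semicolon-separated signal tokens, with `+`
#' marking co-localized channels, e.g. `"O+G;O+B;G+B"` is a nucleus with one
#' intact fusion signal plus an inversion residue. Channel codes: `O` (3' ALK,
#' orange), `G` (5' ALK, green), `B` (EML4, blue).
#'
#' @param x Single string encoding one nucleus.
#' @return Character vector of canonical tokens (possibly length 0).
#' @export
#' @examples
#' parse_tokens("O+G;B+O;G+B")
parse_tokens <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  toks <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  vapply(toks, canonical_token, character(1), USE.NAMES = FALSE)
}

# Deterministic multiset ordering of canonical tokens: sort by the channel
# rank string ("O"->1, "G"->2, "B"->3), so e.g. O < O+G < O+B < G < G+B < B.
sort_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(tokens)
  key <- vapply(strsplit(tokens, "+", fixed = TRUE), function(chs) {
    paste(match(chs, .CHANNELS), collapse = "")
  }, character(1))
  tokens[order(key, method = "radix")]
}

#' Is a token an intact fusion signal?
#'
#' An intact ALK locus shows co-localized 3' orange and 5' green arms; any
#' token carrying both O and G (with or without B) is an intact fusion
#' signal and is interpreted as not rearranged.
#'
#' @param tokens Character vector of canonical tokens.
#' @return Logical vector.
#' @export
is_intact_fusion <- function(tokens) {
  vapply(strsplit(tokens, "+", fixed = TRUE),
         function(chs) all(c("O", "G") %in% chs), logical(1))
}

# Canonical multiset key for a residue (used for signature lookup).
residue_key <- function(tokens) paste(sort_tokens(tokens), collapse = ";")

#' Short label for a residue, e.g. "OB/GB"
#'
#' @param tokens Character vector of canonical tokens.
#' @return Single string; `""` for an empty residue.
#' @export
residue_label <- function(tokens) {
  paste(gsub("+", "", sort_tokens(tokens), fixed = TRUE), collapse = "/")
}

#' The shipped variant signature table
#'
#' Maps every recognised rearranged-residue configuration (the nucleus's
#' signal tokens after removal of intact fusion signals) to its pattern
#' class. Matching is by exact multiset equality, so multiplicities matter:
#' `OB` (one token) is interstitial deletion while `OB/GB` is inversion.
#'
#' Translocation with a non-EML4 partner: `O/GB`, `O/G`, `O/G/B`.
#' ALK/EML4 inversion: `OB/GB`, `OB/G`, `OB/G/B`, `OB/B`.
#' 5' deletion: `O`, `O/B`. Interstitial deletion: `OB`.
#' 3' deletion (green-retaining, orange-lost; recorded but never counted
#' toward positivity): `GB/B`, `GB`, `GB/GB`, `GB/GB/B`.
#'
#' @return Tibble with columns `residue` (canonical multiset key), `label`,
#'   `class`, and `counts_positive`.
#' @export
signature_table <- function() {
  sig <- tibble::tribble(
    ~residue,       ~class,
    "O;G+B",        "TRANSLOCATION",
    "O;G",          "TRANSLOCATION",
    "O;G;B",        "TRANSLOCATION",
    "O+B;G+B",      "INVERSION",
    "O+B;G",        "INVERSION",
    "O+B;G;B",      "INVERSION",
    "O+B;B",        "INVERSION",
    "O",            "FIVE_PRIME_DELETION",
    "O;B",          "FIVE_PRIME_DELETION",
    "O+B",          "INTERSTITIAL_DELETION",
    "G+B;B",        "THREE_PRIME_DELETION",
    "G+B",          "THREE_PRIME_DELETION",
    "G+B;G+B",      "THREE_PRIME_DELETION",
    "G+B;G+B;B",    "THREE_PRIME_DELETION"
  )
  if (anyDuplicated(sig$residue)) {
    stop("signature table is ambiguous: duplicated residue keys")
  }
  sig$label <- vapply(strsplit(sig$residue, ";", fixed = TRUE),
                      residue_label, character(1))
  sig$counts_positive <- sig$class %in% rearrangement_classes()
  sig
}

#' Re-encode tri-color tokens for the dual-color break-apart probe
#'
#' Erases the blue (EML4) channel from each token, preserving
#' co-localization of the remaining channels; tokens that consisted of blue
#' alone disappear.
#'
#' @param tokens Character vector of canonical tokens.
#' @return Character vector of canonical O/G tokens.
#' @export
drop_blue <- function(tokens) {
  out <- vapply(strsplit(tokens, "+", fixed = TRUE), function(chs) {
    chs <- setdiff(chs, "B")
    if (length(chs) == 0L) NA_character_ else paste(chs, collapse = "+")
  }, character(1))
  sort_tokens(out[!is.na(out)])
}
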