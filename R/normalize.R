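#' Normalize a term or text for dictionary matching
#'
#' Applies the package-wide normalization rule used for every lexicon lookup
#' and for duplicate detection: Unicode NFC, lowercase (Latin script),
#' internal whitespace runs collapsed to single spaces, leading/trailing
#' whitespace trimmed. All lexicon surface forms, stop words and matched
#' text pass through this one function so that matching is deterministic
#' across sources.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_term("  Ketotop   Gel ")
normalize_term <- function(x) {
  stopifnot(is.character(x))
  x <- stringi::stri_trans_nfc(enc2utf8(x))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)
  trimws(x)
}
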