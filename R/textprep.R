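#' Clean raw post text
#'
#' Applies, in order: e-mail address removal, URL removal, markup-tag
#' removal, conversion of carriage returns and newlines to spaces, removal
#' of special symbols (every character outside letters, digits and space),
#' and collapsing of space runs. Under the `"target-script-only"` policy,
#' characters outside the configured script (plus digits and spaces) are
#' additionally dropped and stray single-letter fragments (e.g. lone Hangul
#' jamo) are removed — this mirrors corpora restricted to one script.
#' Cleaning is total (never errors) and idempotent.
#'
#' @param raw character vector of raw post bodies (valid UTF-8).
#' @param script_policy `"keep-all"` (default) or `"target-script-only"`.
#' @param script Unicode script name used by the target-script-only policy
#'   (default `"Hangul"`).
#' @return character vector of cleaned text.
#' @export
#' @examples
#' clean_text("pain relief http://x.com <b>now</b>")
clean_text <- function(raw, script_policy = c("keep-all", "target-script-only"),
                       script = "Hangul") {
  script_policy <- match.arg(script_policy)
  stopifnot(is.character(raw))
  x <- enc2utf8(raw)
  if (any(!validUTF8(x))) stop("input is not valid UTF-8", call. = FALSE)
  x <- gsub("[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}", " ", x,
            perl = TRUE)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  x <- gsub("<[^<>]+>", " ", x, perl = TRUE)
  x <- gsub("[\r\n\t]", " ", x, perl = TRUE)
  x <- gsub("[^\\p{L}\\p{N} ]", " ", x, perl = TRUE)
  if (script_policy == "target-script-only") {
    x <- gsub(paste0("[^\\p{", script, "}\\p{N} ]"), " ", x, perl = TRUE)
    # lone syllabic fragments: single in-script characters standing alone
    x <- gsub(paste0("(?<![^ ])\\p{", script, "}(?![^ ])"), " ", x,
              perl = TRUE)
  }
  x <- gsub(" {2,}", " ", x)
  trimws(x)
}

#' Default regex word tokenizer
#'
#' Splits on runs of characters that are neither letters nor digits. Returns
#' bare tokens (no part-of-speech tags), so downstream noun filtering is a
#' no-op. Any callable with the same contract — `function(text)` returning
#' either a character vector of tokens or a list with elements `token` and
#' `pos` — can replace it, e.g. a wrapper around a Korean morphological
#' analyzer.
#'
#' @param text a single cleaned string.
#' @return character vector of tokens.
#' @export
default_tokenizer <- function(text) {
  if (!nzchar(text)) return(character())
  toks <- strsplit(text, "[^\\p{L}\\p{N}]+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Tokenize cleaned text with drug-name protection
#'
#' Spans matching `protect` lexicon terms are replaced by atomic
#' placeholders before the tokenizer runs and restored as single tokens
#' afterwards, so multi-word drug names are never split by the analyzer.
#' When the tokenizer reports part-of-speech tags, only noun-tagged tokens
#' (tags starting with `"N"`) are kept, mirroring noun extraction; a bare
#' token vector keeps everything.
#'
#' @param clean a single cleaned string (output of [clean_text()]).
#' @param tokenizer analyzer callable; see [default_tokenizer()] for the
#'   contract.
#' @param protect a `drug_lexicon` whose terms must survive as single
#'   tokens, or `NULL`.
#' @param post_id identifier attached to the resulting document (used in
#'   diagnostics when the tokenizer fails).
#' @return a `token_doc`: list with `post_id`, `tokens` (normalized,
#'   ordered, no empties) and `protected_terms` (terms found
#'   pre-tokenization).
#' @export
tokenize <- function(clean, tokenizer = default_tokenizer, protect = NULL,
                     post_id = NA_character_) {
  stopifnot(is.character(clean), length(clean) == 1L, is.function(tokenizer))
  text <- normalize_term(clean)
  protected <- character()
  if (!is.null(protect) && nzchar(text)) {
    stopifnot(inherits(protect, "drug_lexicon"))
    m <- match_terms(text, protect)
    if (nrow(m)) {
      protected <- unique(m$surface_term)
      # placeholders are pure alphanumerics so no tokenizer can split them;
      # replace right-to-left so earlier offsets stay valid
      for (i in rev(seq_len(nrow(m)))) {
        ph <- sprintf("qzqprotectedq%dqzq",
                      match(m$surface_term[i], protected))
        text <- paste0(substr(text, 1L, m$start[i]), ph,
                       substring(text, m$end[i] + 1L))
      }
    }
  }
  toks <- tryCatch(tokenizer(text), error = function(e) {
    stop("tokenizer failed on post ", post_id, ": ", conditionMessage(e),
         call. = FALSE)
  })
  is_ph <- function(t) grepl("^qzqprotectedq\\d+qzq$", t)
  if (is.list(toks) && !is.null(toks$token)) {
    pos <- toks$pos
    toks <- as.character(toks$token)
    # noun filter never drops a protected drug name
    if (!is.null(pos)) {
      toks <- toks[startsWith(as.character(pos), "N") | is_ph(toks)]
    }
  } else {
    toks <- as.character(toks)
  }
  toks <- toks[nzchar(toks)]
  # restore protected placeholders as single tokens
  if (length(protected)) {
    hit <- is_ph(toks)
    toks[hit] <- protected[as.integer(sub("^qzqprotectedq(\\d+)qzq$", "\\1",
                                          toks[hit]))]
  }
  toks <- normalize_term(toks)
  structure(list(post_id = post_id, tokens = toks[nzchar(toks)],
                 protected_terms = protected),
            class = "token_doc")
}

#' @export
print.token_doc <- function(x, ...) {
  cat("<token_doc> post ", x$post_id, ": ", length(x$tokens), " token(s)\n",
      sep = "")
  invisible(x)
}

#' Remove stop words from a tokenized document
#'
#' Every token present in the stop-word set is removed; the order of the
#' remainder is preserved and the number removed is recorded in the
#' `n_removed` attribute for reporting. A document whose tokens are all
#' stop words becomes an empty (but retained) document — dropping posts is
#' the filter cascade's job, not this function's.
#'
#' @param doc a `token_doc`.
#' @param stops a `stopword_set`.
#' @return the filtered `token_doc`.
#' @export
filter_stopwords <- function(doc, stops) {
  stopifnot(inherits(doc, "token_doc"), inherits(stops, "stopword_set"))
  keep <- !(doc$tokens %in% stops$words)
  out <- doc
  out$tokens <- doc$tokens[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
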