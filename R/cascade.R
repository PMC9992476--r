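#' Advertisement filter
#'
#' A post is dropped when it contains at least one configured promotional
#' token (matched on normalized text at word boundaries) or when its
#' pre-cleaning URL count exceeds `max_urls`. Both knobs are configurable;
#' an empty token list with `max_urls = Inf` is the identity.
#'
#' @param posts corpus tibble (cleaned; `n_urls` column used when present,
#'   otherwise URLs are counted in `raw_text`/`text`).
#' @param promo_tokens character vector of promotional words/phrases.
#' @param max_urls posts with more URLs than this are dropped (default
#'   `Inf`).
#' @return filtered tibble; dropped ids in attribute `dropped`.
#' @export
remove_ads <- function(posts, promo_tokens = character(), max_urls = Inf) {
  stopifnot(is.data.frame(posts))
  n_urls <- if ("n_urls" %in% names(posts)) posts$n_urls else {
    count_urls(if ("raw_text" %in% names(posts)) posts$raw_text
               else posts$text)
  }
  is_ad <- n_urls > max_urls
  if (length(promo_tokens)) {
    # promo tokens undergo the same cleaning as post text, so configured
    # forms like "event-giveaway" match their cleaned occurrence
    promo <- normalize_term(clean_text(promo_tokens))
    promo <- promo[nzchar(promo)]
    norm <- normalize_term(ifelse(is.na(posts$text), "", posts$text))
    for (p in promo) {
      pat <- paste0("(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\?.])",
                                             "\\\\\\1", p),
                    "(?![[:alnum:]])")
      is_ad <- is_ad | grepl(pat, norm, perl = TRUE)
    }
  }
  out <- posts[!is_ad, , drop = FALSE]
  attr(out, "dropped") <- posts$id[is_ad]
  out
}

#' Keep posts mentioning lexicon terms
#'
#' Retains posts in which [match_terms()] finds at least `min_count`
#' occurrences of lexicon surface terms — e.g. posts containing the drug
#' name at least once, then posts containing a side-effect word.
#'
#' @param posts corpus tibble (cleaned).
#' @param lex `drug_lexicon` or `adr_lexicon`.
#' @param min_count minimum number of matches (integer >= 1).
#' @return filtered tibble; dropped ids in attribute `dropped`.
#' @export
require_mention <- function(posts, lex, min_count = 1L) {
  stopifnot(is.data.frame(posts))
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1) {
    stop("min_count must be >= 1", call. = FALSE)
  }
  n_hit <- vapply(ifelse(is.na(posts$text), "", posts$text), function(tx) {
    nrow(match_terms(tx, lex))
  }, integer(1), USE.NAMES = FALSE)
  keep <- n_hit >= min_count
  out <- posts[keep, , drop = FALSE]
  attr(out, "dropped") <- posts$id[!keep]
  out
}

#' Collapse duplicate posts
#'
#' Posts with identical normalized text are collapsed to the earliest by
#' date (ties broken by lexicographically smallest id); the surviving
#' posts keep their original relative order. Idempotent.
#'
#' @param posts corpus tibble.
#' @return deduplicated tibble; dropped ids in attribute `dropped`.
#' @export
deduplicate <- function(posts) {
  stopifnot(is.data.frame(posts))
  if (nrow(posts) == 0L) {
    attr(posts, "dropped") <- character()
    return(posts)
  }
  key <- normalize_term(ifelse(is.na(posts$text), "", posts$text))
  date <- suppressWarnings(as.Date(posts$date))
  date_key <- ifelse(is.na(date), "9999-12-31", format(date))
  ord <- order(key, date_key, posts$id)
  first <- ord[!duplicated(key[ord])]
  keep <- sort(first)
  out <- posts[keep, , drop = FALSE]
  attr(out, "dropped") <- posts$id[-keep]
  if (length(keep) == nrow(posts)) attr(out, "dropped") <- character()
  out
}

#' Run the full post-filtering cascade
#'
#' Applies, in order: advertisement removal, drug-mention requirement,
#' ADR-mention requirement, duplicate removal. Returns the surviving posts
#' and a stage-by-stage report whose counts are non-increasing and whose
#' dropped-id sets are disjoint. The report also carries the total token
#' count across surviving posts (whitespace tokens of the cleaned text),
#' mirroring corpus-size reporting alongside post counts.
#'
#' @param posts cleaned corpus tibble.
#' @param drug_lex `drug_lexicon`.
#' @param adr_lex `adr_lexicon`.
#' @param config list with optional `promo_tokens`, `max_urls`,
#'   `min_drug_mentions`, `min_adr_mentions`.
#' @return list with `posts` (survivors) and `report` (a `filter_report`).
#' @export
run_cascade <- function(posts, drug_lex, adr_lex, config = list()) {
  stopifnot(is.data.frame(posts))
  cfg <- utils::modifyList(
    list(promo_tokens = character(), max_urls = Inf,
         min_drug_mentions = 1L, min_adr_mentions = 1L),
    config)
  stages <- c("input", "ad_removed", "drug_mention", "adr_mention", "deduped")
  counts <- integer(5); names(counts) <- stages
  dropped <- stats::setNames(vector("list", 4L), stages[-1])
  counts["input"] <- nrow(posts)

  cur <- remove_ads(posts, cfg$promo_tokens, cfg$max_urls)
  dropped$ad_removed <- attr(cur, "dropped")
  counts["ad_removed"] <- nrow(cur)

  cur <- require_mention(cur, drug_lex, cfg$min_drug_mentions)
  dropped$drug_mention <- attr(cur, "dropped")
  counts["drug_mention"] <- nrow(cur)

  cur <- require_mention(cur, adr_lex, cfg$min_adr_mentions)
  dropped$adr_mention <- attr(cur, "dropped")
  counts["adr_mention"] <- nrow(cur)

  cur <- deduplicate(cur)
  dropped$deduped <- attr(cur, "dropped")
  counts["deduped"] <- nrow(cur)

  n_words <- if (nrow(cur) == 0L) 0L else {
    sum(vapply(strsplit(ifelse(is.na(cur$text), "", cur$text),
                        "[[:space:]]+"),
               function(t) sum(nzchar(t)), integer(1)))
  }
  report <- structure(
    list(stage_counts = counts, dropped = dropped, n_words = n_words,
         config_fingerprint = rlang::hash(cfg)),
    class = "filter_report")
  list(posts = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (s in names(x$stage_counts)) {
    cat(sprintf("  %-12s %d\n", s, x$stage_counts[[s]]))
  }
  cat("  words kept  ", x$n_words, "\n", sep = "")
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  obj <- list(
    stage_counts = as.list(report$stage_counts),
    dropped = lapply(report$dropped, as.character),
    n_words = report$n_words,
    config_fingerprint = report$config_fingerprint)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
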