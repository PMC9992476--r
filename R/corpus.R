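#' Read a post corpus from JSONL
#'
#' One JSON object per line with keys `id`, `channel`, `date`, `text`
#' (additional keys are kept). Dates are stored as ISO-8601 strings;
#' unparseable or absent dates become `NA`.
#'
#' @param path JSONL file path.
#' @return tibble with one row per post.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(id = character(), channel = character(),
                          date = character(), text = character()))
  }
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  keys <- unique(unlist(lapply(recs, names)))
  cols <- lapply(keys, function(k) {
    vapply(recs, function(r) {
      v <- r[[k]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  names(cols) <- keys
  posts <- tibble::as_tibble(cols)
  for (k in c("id", "channel", "date", "text")) {
    if (!k %in% names(posts)) posts[[k]] <- NA_character_
  }
  if (anyDuplicated(posts$id)) {
    stop("duplicate post id(s): ",
         paste(unique(posts$id[duplicated(posts$id)]), collapse = ", "),
         call. = FALSE)
  }
  posts
}

#' Write a post corpus as JSONL
#'
#' Deterministic inverse of [read_posts()]: identical tibbles yield
#' byte-identical files.
#'
#' @param posts tibble of posts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    rec <- as.list(posts[i, ])
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                             digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Clean every post body in a corpus
#'
#' Adds/overwrites the `text` column with [clean_text()] output, keeps the
#' original body in `raw_text`, and records the pre-cleaning URL count per
#' post in `n_urls` (the advertisement filter uses pre-cleaning counts).
#'
#' @param posts tibble of posts with a `text` column.
#' @param ... passed to [clean_text()].
#' @return tibble with `text` cleaned and `raw_text`, `n_urls` added.
#' @export
clean_corpus <- function(posts, ...) {
  stopifnot(is.data.frame(posts), "text" %in% names(posts))
  raw <- posts$text
  if (!"raw_text" %in% names(posts)) posts$raw_text <- raw
  posts$n_urls <- count_urls(posts$raw_text)
  posts$text <- clean_text(ifelse(is.na(raw), "", raw), ...)
  posts
}

count_urls <- function(x) {
  x <- ifelse(is.na(x), "", x)
  hits <- gregexpr("(https?://|www\\.)[^[:space:]]+", x, perl = TRUE)
  vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), integer(1))
}

#' Tokenize every post of a cleaned corpus
#'
#' @param posts cleaned corpus tibble.
#' @param tokenizer analyzer callable (see [default_tokenizer()]).
#' @param protect optional `drug_lexicon` of terms to keep atomic.
#' @param stops optional `stopword_set` removed after tokenization.
#' @return list of `token_doc`, one per post, named by post id.
#' @export
tokenize_corpus <- function(posts, tokenizer = default_tokenizer,
                            protect = NULL, stops = NULL) {
  docs <- lapply(seq_len(nrow(posts)), function(i) {
    tokenize(posts$text[i], tokenizer = tokenizer, protect = protect,
             post_id = posts$id[i])
  })
  if (!is.null(stops)) docs <- lapply(docs, filter_stopwords, stops = stops)
  names(docs) <- posts$id
  docs
}
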