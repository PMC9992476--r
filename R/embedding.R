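#' Skip-gram training configuration
#'
#' Defaults follow canonical word2vec practice where the method itself
#' leaves them open: 5 negative samples, linear learning-rate decay from
#' 0.025, dynamic window radius drawn uniformly in `[1, window]` per
#' center token, negatives drawn from the unigram distribution raised to
#' the 3/4 power. The study-scale profile is `dim = 300`, `window = 10`;
#' the package default is a desk-scale `dim = 50`, `window = 5`, which
#' preserves neighborhood structure on corpora of a few thousand posts.
#'
#' @param dim embedding dimensionality (>= 1).
#' @param window maximum context radius in tokens (>= 1).
#' @param negatives negative samples per positive pair (>= 1).
#' @param epochs passes over the corpus.
#' @param learning_rate initial learning rate (linear decay to 1e-4 of it).
#' @param min_count tokens rarer than this are dropped from the vocabulary.
#' @param seed integer seed; fixed seed gives bit-identical vectors
#'   (training is single-threaded).
#' @return list of class `sgns_config`.
#' @export
sgns_config <- function(dim = 50L, window = 5L, negatives = 5L,
                        epochs = 10L, learning_rate = 0.025,
                        min_count = 1L, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, negatives >= 1, epochs >= 1,
            learning_rate > 0, min_count >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negatives = as.integer(negatives),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 min_count = as.integer(min_count),
                 seed = as.integer(seed)),
            class = "sgns_config")
}

#' Train skip-gram negative-sampling embeddings
#'
#' Stochastic-gradient training of the skip-gram objective with negative
#' sampling: for a center token w and context token c the model maximizes
#' `log sigma(u_c . v_w) + sum_k log sigma(-u_nk . v_w)` over k negatives
#' drawn from the 3/4-power unigram distribution. Multi-word protected
#' terms are single vocabulary items because tokenization keeps them
#' atomic.
#'
#' @param docs list of `token_doc` (or a plain list of character token
#'   vectors).
#' @param config an `sgns_config`.
#' @return an `sgns_model`: list with `vocabulary` (tibble: `term`,
#'   `freq`), `input_vectors` and `output_vectors` (|vocab| x dim, rows
#'   named by term), `config`.
#' @export
train_sgns <- function(docs, config = sgns_config()) {
  stopifnot(inherits(config, "sgns_config"))
  toks <- lapply(docs, function(d) {
    if (inherits(d, "token_doc")) d$tokens else as.character(d)
  })
  all_tok <- unlist(toks, use.names = FALSE)
  if (length(all_tok) == 0L) {
    stop("empty corpus: no tokens to train on", call. = FALSE)
  }
  freq <- table(all_tok)
  freq <- freq[freq >= config$min_count]
  vocab <- sort(names(freq))
  if (length(vocab) < 2L) {
    stop("effective vocabulary has fewer than 2 distinct tokens",
         call. = FALSE)
  }
  freq <- as.numeric(freq[vocab])
  enc <- lapply(toks, function(tk) {
    id <- match(tk, vocab)
    as.integer(id[!is.na(id)] - 1L)
  })
  enc <- enc[lengths(enc) > 0L]
  fit <- sgns_train_cpp(enc, freq, config$dim, config$window,
                        config$negatives, config$epochs,
                        config$learning_rate, as.double(config$seed))
  rownames(fit$input_vectors) <- vocab
  rownames(fit$output_vectors) <- vocab
  structure(list(vocabulary = tibble::tibble(term = vocab, freq = freq),
                 input_vectors = fit$input_vectors,
                 output_vectors = fit$output_vectors,
                 config = config),
            class = "sgns_model")
}

#' @export
print.sgns_model <- function(x, ...) {
  cat("<sgns_model> ", nrow(x$vocabulary), " term(s), dim ",
      x$config$dim, ", window ", x$config$window, "\n", sep = "")
  invisible(x)
}

#' Nearest neighbors by cosine similarity
#'
#' Top-k vocabulary terms most cosine-similar to the anchor's input
#' vector, the anchor itself excluded; exact similarity ties are broken
#' lexicographically.
#'
#' @param model an `sgns_model`.
#' @param anchor vocabulary term (normalized before lookup).
#' @param k number of neighbors (k = 0 gives an empty result).
#' @return tibble with columns `term`, `similarity`, ordered by
#'   decreasing similarity.
#' @export
neighbors <- function(model, anchor, k = 10L) {
  stopifnot(inherits(model, "sgns_model"), k >= 0)
  anchor <- normalize_term(anchor)
  vocab <- model$vocabulary$term
  if (!anchor %in% vocab) {
    d <- utils::adist(anchor, vocab)[1, ]
    near <- vocab[order(d)][seq_len(min(3L, length(vocab)))]
    stop("anchor '", anchor, "' not in vocabulary; nearest forms: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  if (k == 0L) return(tibble::tibble(term = character(),
                                     similarity = numeric()))
  W <- model$input_vectors
  nrm <- sqrt(rowSums(W^2))
  nrm[nrm == 0] <- 1
  v <- W[anchor, ] / nrm[anchor]
  sims <- as.numeric(W %*% v) / nrm
  names(sims) <- vocab
  sims <- sims[vocab != anchor]
  ord <- order(-sims, names(sims))
  top <- ord[seq_len(min(k, length(sims)))]
  tibble::tibble(term = names(sims)[top], similarity = unname(sims[top]))
}

#' Detect ADR words in embedding neighborhoods and count their mentions
#'
#' The detected set is the union over anchors of each anchor's top-k
#' cosine neighbors, intersected with the ADR lexicon's surface forms.
#' Each detected term's count is the number of posts (already filtered to
#' the target drug) in which the term occurs at least once. Unknown
#' anchors are skipped with a warning; if every anchor is unknown, an
#' error is raised.
#'
#' @param model an `sgns_model`.
#' @param anchors character vector of anchor terms (typically the literal
#'   token for "side effects" plus the drug surface terms).
#' @param adr_lex an `adr_lexicon`.
#' @param k neighbors per anchor (default 100).
#' @param posts drug-filtered corpus tibble used for mention counting.
#' @return named integer vector: detected ADR surface term -> number of
#'   posts mentioning it.
#' @export
detect_adr_words <- function(model, anchors, adr_lex, k = 100L, posts) {
  stopifnot(inherits(model, "sgns_model"), inherits(adr_lex, "adr_lexicon"),
            is.data.frame(posts))
  anchors <- normalize_term(anchors)
  known <- anchors[anchors %in% model$vocabulary$term]
  if (length(known) == 0L) {
    stop("no anchor found in the embedding vocabulary: ",
         paste(anchors, collapse = ", "), call. = FALSE)
  }
  if (length(known) < length(anchors)) {
    warning("anchor(s) not in vocabulary, skipped: ",
            paste(setdiff(anchors, known), collapse = ", "), call. = FALSE)
  }
  neigh <- unique(unlist(lapply(known, function(a) {
    neighbors(model, a, k = k)$term
  })))
  detected <- intersect(neigh, surface_terms(adr_lex))
  if (length(detected) == 0L) {
    return(stats::setNames(integer(), character()))
  }
  detected <- sort(detected)
  texts <- normalize_term(ifelse(is.na(posts$text), "", posts$text))
  counts <- vapply(detected, function(tm) {
    pat <- paste0("(?<![[:alnum:]])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tm),
                  "(?![[:alnum:]])")
    sum(grepl(pat, texts, perl = TRUE))
  }, integer(1))
  counts
}

#' Persist an embedding model in word2vec text format
#'
#' First line: `<vocab> <dim>`; then one line per term with its input
#' vector. [read_sgns_model()] restores a model usable for neighbor
#' queries (output vectors are not persisted).
#'
#' @param model an `sgns_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sgns_model <- function(model, path) {
  stopifnot(inherits(model, "sgns_model"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  W <- model$input_vectors
  writeLines(paste(nrow(W), ncol(W)), con, useBytes = TRUE)
  for (i in seq_len(nrow(W))) {
    writeLines(paste(rownames(W)[i],
                     paste(formatC(W[i, ], format = "g", digits = 17),
                           collapse = " ")),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a word2vec-text-format model
#'
#' @param path file written by [write_sgns_model()] (terms must not
#'   contain spaces unless they were protected multi-word terms, which are
#'   stored with underscores).
#' @return an `sgns_model` with `output_vectors = NULL`.
#' @export
read_sgns_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  n <- hdr[1]; dim <- hdr[2]
  terms <- character(n)
  W <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], " ")[[1]]
    nv <- length(parts)
    terms[i] <- paste(parts[seq_len(nv - dim)], collapse = " ")
    W[i, ] <- as.numeric(parts[(nv - dim + 1L):nv])
  }
  rownames(W) <- terms
  structure(list(vocabulary = tibble::tibble(term = terms, freq = NA_real_),
                 input_vectors = W, output_vectors = NULL,
                 config = NULL),
            class = "sgns_model")
}
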