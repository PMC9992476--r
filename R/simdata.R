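#' Synthetic-corpus configuration
#'
#' Describes a post corpus with a Zipf background vocabulary, drug-term
#' mentions at a configurable rate, ADR co-mentions elevated in drug posts
#' (planted associations), advertisement posts and verbatim duplicates —
#' the corpus structure the pipeline is designed for, without any natural
#' language. Each planted pair is a list
#' `(drug, adr, p_drug, p_adr_given_drug, p_adr_background)`: the
#' probability a post mentions the drug, that a drug post mentions the
#' ADR, and that a non-drug post mentions it.
#'
#' @param n_posts number of base posts (duplicates are appended on top).
#' @param background_vocab_size size of the Zipf background vocabulary.
#' @param zipf_exponent Zipf exponent of the background distribution
#'   (default 1.1).
#' @param post_length mean background tokens per post (Poisson).
#' @param drug_terms drug surface terms available to the generator.
#' @param planted_pairs list of planted (drug, adr, p_drug,
#'   p_adr_given_drug, p_adr_background) associations.
#' @param context_vocab_size per planted pair, the size of a dedicated
#'   "symptom talk" vocabulary inserted around both the drug and the ADR
#'   token (2 draws on each side). Posts mentioning a drug or its ADR use
#'   the same characteristic words, which is what lets an embedding place
#'   the pair in one neighborhood; set to 0 to plant bare adjacency only.
#' @param ad_fraction fraction of posts that are advertisements (they get
#'   a promotional token and a URL in the raw text).
#' @param promo_tokens promotional tokens inserted into ad posts.
#' @param duplicate_fraction fraction of posts duplicated verbatim under
#'   fresh ids (in `[0, 1)`).
#' @param seed integer seed; the same seed reproduces the corpus
#'   byte-identically.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_posts = 1000L, background_vocab_size = 200L,
                       zipf_exponent = 1.1, post_length = 20,
                       drug_terms = "ketoprofen",
                       planted_pairs = list(
                         list(drug = "ketoprofen", adr = "rash",
                              p_drug = 0.2, p_adr_given_drug = 0.7,
                              p_adr_background = 0.05)),
                       context_vocab_size = 8L,
                       ad_fraction = 0.1,
                       promo_tokens = c("giveaway", "coupon"),
                       duplicate_fraction = 0.05, seed = 1L) {
  stopifnot(n_posts >= 0, background_vocab_size >= 1, zipf_exponent > 0,
            post_length > 0, context_vocab_size >= 0,
            ad_fraction >= 0, ad_fraction < 1,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  for (pp in planted_pairs) {
    probs <- c(pp$p_drug, pp$p_adr_given_drug, pp$p_adr_background)
    if (any(probs < 0 | probs > 1) || length(probs) != 3L) {
      stop("planted pair probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (!pp$drug %in% drug_terms) {
      stop("planted drug '", pp$drug, "' not in drug_terms", call. = FALSE)
    }
  }
  structure(list(n_posts = as.integer(n_posts),
                 background_vocab_size = as.integer(background_vocab_size),
                 zipf_exponent = zipf_exponent, post_length = post_length,
                 drug_terms = drug_terms, planted_pairs = planted_pairs,
                 context_vocab_size = as.integer(context_vocab_size),
                 ad_fraction = ad_fraction, promo_tokens = promo_tokens,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic post corpus with planted associations
#'
#' Per base post: background tokens are drawn from a Zipf distribution
#' over `bgNNNN` words; for each planted pair, the drug is mentioned with
#' `p_drug` and the ADR with `p_adr_given_drug` in drug posts or
#' `p_adr_background` otherwise. A planted ADR token is injected within a
#' few tokens of its drug token so embedding training can learn the
#' proximity. Ad posts carry a promotional token and a URL in the raw
#' text. Finally `duplicate_fraction` of the posts are copied verbatim
#' under fresh ids. The ground-truth record stores every post's planted
#' memberships.
#'
#' @param config a `sim_config`.
#' @return list with `posts` (tibble: id, channel, date, text, raw_text)
#'   and `truth` (tibble: id, is_ad, duplicate_of, plus logical columns
#'   `drug_<term>` / `adr_<term>` per planted mention).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_posts
  empty <- tibble::tibble(id = character(), channel = character(),
                          date = character(), text = character(),
                          raw_text = character())
  if (n == 0L) {
    return(list(posts = empty,
                truth = tibble::tibble(id = character(), is_ad = logical(),
                                       duplicate_of = character())))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  V <- config$background_vocab_size
  bg_vocab <- sprintf("bg%04d", seq_len(V))
  zipf_p <- seq_len(V)^(-config$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)

  ids <- sprintf("p%06d", seq_len(n))
  dates <- format(as.Date("2020-01-01") +
                    sample.int(365L, n, replace = TRUE) - 1L)
  channels <- sample(c("blog", "cafe"), n, replace = TRUE)
  is_ad <- stats::runif(n) < config$ad_fraction

  npairs <- length(config$planted_pairs)
  drug_flags <- matrix(FALSE, n, npairs)
  adr_flags <- matrix(FALSE, n, npairs)
  for (j in seq_len(npairs)) {
    pp <- config$planted_pairs[[j]]
    drug_flags[, j] <- stats::runif(n) < pp$p_drug
    p_adr <- ifelse(drug_flags[, j], pp$p_adr_given_drug,
                    pp$p_adr_background)
    adr_flags[, j] <- stats::runif(n) < p_adr
  }

  cxv <- config$context_vocab_size
  cx_vocab <- lapply(seq_len(npairs), function(j) {
    if (cxv > 0L) sprintf("cx%d%02d", j, seq_len(cxv)) else character()
  })
  # a term plus its surrounding "symptom talk" context words
  with_context <- function(term, j) {
    if (cxv == 0L) return(term)
    c(sample(cx_vocab[[j]], 2L, replace = TRUE), term,
      sample(cx_vocab[[j]], 2L, replace = TRUE))
  }
  texts <- character(n)
  raw <- character(n)
  for (i in seq_len(n)) {
    len <- max(3L, stats::rpois(1L, config$post_length))
    toks <- sample(bg_vocab, len, replace = TRUE, prob = zipf_p)
    for (j in seq_len(npairs)) {
      pp <- config$planted_pairs[[j]]
      if (drug_flags[i, j]) {
        pos <- sample.int(length(toks) + 1L, 1L)
        ins <- with_context(pp$drug, j)
        if (adr_flags[i, j]) {
          # the ADR mention stays within embedding-window reach of the drug
          ins <- c(ins, with_context(pp$adr, j))
        }
        toks <- append(toks, ins, after = pos - 1L)
      } else if (adr_flags[i, j]) {
        pos <- sample.int(length(toks) + 1L, 1L)
        toks <- append(toks, with_context(pp$adr, j), after = pos - 1L)
      }
    }
    if (is_ad[i] && length(config$promo_tokens)) {
      toks <- c(sample(config$promo_tokens, 1L), toks)
    }
    texts[i] <- paste(toks, collapse = " ")
    raw[i] <- if (is_ad[i]) {
      paste0(texts[i], " http://promo.example.com/", i)
    } else {
      texts[i]
    }
  }

  posts <- tibble::tibble(id = ids, channel = channels, date = dates,
                          text = raw, raw_text = raw)
  truth <- tibble::tibble(id = ids, is_ad = is_ad,
                          duplicate_of = NA_character_)
  for (j in seq_len(npairs)) {
    pp <- config$planted_pairs[[j]]
    truth[[paste0("drug_", pp$drug)]] <- drug_flags[, j]
    truth[[paste0("adr_", pp$adr)]] <- adr_flags[, j]
  }

  n_dup <- floor(config$duplicate_fraction * n)
  if (n_dup > 0L) {
    src <- sample.int(n, n_dup, replace = FALSE)
    dup_posts <- posts[src, ]
    dup_posts$id <- sprintf("d%06d", seq_len(n_dup))
    # later date so the original survives deduplication
    dup_posts$date <- format(as.Date(posts$date[src]) + 30L)
    posts <- rbind(posts, dup_posts)
    dup_truth <- truth[src, ]
    dup_truth$id <- dup_posts$id
    dup_truth$duplicate_of <- ids[src]
    truth <- rbind(truth, dup_truth)
  }
  list(posts = posts, truth = truth)
}

#' Closed-form expected rule metrics for a planted pair
#'
#' Under the generator's independent-Bernoulli model, the drug => ADR rule
#' for planted pair `i` has
#' `support = p_drug * p_adr_given_drug`,
#' `confidence = p_adr_given_drug`, and
#' `lift = p_adr_given_drug / (p_drug * p_adr_given_drug +
#' (1 - p_drug) * p_adr_background)`.
#' These are the population values the mined empirical metrics converge to
#' on ad-free, duplicate-free corpora.
#'
#' @param config a `sim_config`.
#' @param pair index into `config$planted_pairs`.
#' @return list with `support`, `confidence`, `lift`.
#' @export
expected_rule_metrics <- function(config, pair = 1L) {
  stopifnot(inherits(config, "sim_config"),
            pair >= 1L, pair <= length(config$planted_pairs))
  pp <- config$planted_pairs[[pair]]
  p_adr <- pp$p_drug * pp$p_adr_given_drug +
    (1 - pp$p_drug) * pp$p_adr_background
  list(support = pp$p_drug * pp$p_adr_given_drug,
       confidence = pp$p_adr_given_drug,
       lift = if (p_adr > 0) pp$p_adr_given_drug / p_adr else NaN)
}
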