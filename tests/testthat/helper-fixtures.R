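# Shared fixtures and independent oracles, built in code at test time.

extdata <- function(name) {
  system.file("extdata", name, package = "snsminer", mustWork = TRUE)
}

demo_drug_lex <- function() load_lexicon(extdata("drug_lexicon_ketoprofen.tsv"), "drug")
demo_adr_lex <- function() load_lexicon(extdata("adr_lexicon_synthetic.tsv"), "adr")
demo_posts <- function() clean_corpus(read_posts(extdata("posts_demo.jsonl")))
demo_promo <- function() readLines(extdata("promo_tokens.txt"))

# The hand-worked rule corpus: 10 posts, drug D in 4, ADR A in 3, both in 3.
rule_fixture_posts <- function() {
  texts <- c("ketoprofen rash", "ketoprofen rash bg1", "bg2 ketoprofen rash",
             "ketoprofen bg3", "bg4 bg5", "bg6", "bg7", "bg8", "bg9", "bg10")
  tibble::tibble(id = sprintf("p%02d", seq_along(texts)), channel = "blog",
                 date = NA_character_, text = texts)
}

rule_fixture_lexicons <- function() {
  list(drug = drug_lexicon("ketoprofen", "ketoprofen"),
       adr = adr_lexicon("rash", "Rash", "Skin and appendages disorders",
                         "terminology_a"))
}

# Random token corpus over disjoint single-token drug/ADR/background
# vocabularies; post 1 always carries one drug and one ADR term so the
# incidence matrix is well-formed.
random_rule_corpus <- function(n_posts, n_drug, n_adr) {
  drugs <- sprintf("drg%02d", seq_len(n_drug))
  adrs <- sprintf("adr%02d", seq_len(n_adr))
  bg <- sprintf("bgw%02d", 1:6)
  texts <- vapply(seq_len(n_posts), function(i) {
    toks <- c(drugs[stats::runif(n_drug) < 0.35],
              adrs[stats::runif(n_adr) < 0.3],
              sample(bg, 3, replace = TRUE))
    if (i == 1L) toks <- unique(c(drugs[1], adrs[1], toks))
    paste(sample(toks), collapse = " ")
  }, character(1))
  list(posts = tibble::tibble(id = sprintf("r%03d", seq_len(n_posts)),
                              channel = "blog", date = NA_character_,
                              text = texts),
       drug = drug_lexicon(rep("ing", n_drug), drugs),
       adr = adr_lexicon(adrs, paste0("PT_", adrs),
                         rep("SOC_X", n_adr), "terminology_a"))
}

# Independent brute-force rule miner: presence by token membership, every
# pair enumerated with plain loops, metrics straight from the definitions.
brute_force_rules <- function(posts, drug_terms, adr_terms, thresholds) {
  tok <- lapply(strsplit(tolower(posts$text), " ", fixed = TRUE), unique)
  n_total <- nrow(posts)
  has <- function(term) vapply(tok, function(t) term %in% t, logical(1))
  observed <- function(terms) terms[vapply(terms, function(t) any(has(t)),
                                           logical(1))]
  drug_terms <- observed(drug_terms)
  adr_terms <- observed(adr_terms)
  out <- list()
  for (d in drug_terms) {
    for (a in adr_terms) {
      in_d <- has(d); in_a <- has(a)
      n_ante <- sum(in_d); n_cons <- sum(in_a); n_both <- sum(in_d & in_a)
      if (n_ante == 0) next
      support <- n_both / n_total
      confidence <- n_both / n_ante
      lift <- confidence / (n_cons / n_total)
      if (support >= thresholds$min_support &&
          confidence >= thresholds$min_confidence &&
          lift >= thresholds$min_lift) {
        out[[length(out) + 1L]] <- data.frame(
          antecedent = d, consequent = a, n_both = n_both, n_ante = n_ante,
          n_cons = n_cons, n_total = n_total, support = support,
          confidence = confidence, lift = lift)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(antecedent = character(), consequent = character(),
                      n_both = integer(), n_ante = integer(),
                      n_cons = integer(), n_total = integer(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$antecedent, res$consequent), , drop = FALSE]
}

# Two-topic corpus for embedding neighborhood recovery: disjoint topic
# vocabularies plus shared function words.
two_topic_corpus <- function(seed, n_docs = 200L, doc_len = 25L) {
  set.seed(seed)
  t1 <- sprintf("alpha%02d", 1:8)
  t2 <- sprintf("beta%02d", 1:8)
  fw <- sprintf("func%d", 1:3)
  docs <- lapply(seq_len(n_docs), function(i) {
    vocab <- if (i %% 2L) t1 else t2
    sample(c(vocab, fw), doc_len, replace = TRUE)
  })
  list(docs = docs, topic1 = t1, topic2 = t2, functionwords = fw)
}

# Hand-set 2-d embedding model for cosine arithmetic checks.
hand_model <- function(vectors) {
  terms <- rownames(vectors)
  structure(list(vocabulary = tibble::tibble(term = terms,
                                             freq = rep(1, length(terms))),
                 input_vectors = vectors, output_vectors = vectors,
                 config = sgns_config()),
            class = "sgns_model")
}
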