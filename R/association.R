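#' Named rule-threshold profiles
#'
#' Two profiles ship with the package, matching the two settings used for
#' signal filtering and for chord-diagram export respectively:
#' `"strict"` = support >= 0.015, confidence >= 0.6, lift >= 1.0;
#' `"chord"`  = support >= 0.01,  confidence >= 0.6, lift >= 1.0.
#'
#' @param profile `"strict"` (default) or `"chord"`, or `NULL` to build a
#'   custom profile from the remaining arguments.
#' @param min_support,min_confidence,min_lift custom thresholds (used when
#'   `profile` is `NULL`).
#' @return list with `min_support`, `min_confidence`, `min_lift`.
#' @export
rule_thresholds <- function(profile = c("strict", "chord"),
                            min_support = 0.015, min_confidence = 0.6,
                            min_lift = 1.0) {
  if (!is.null(profile)) {
    profile <- match.arg(profile)
    return(switch(profile,
                  strict = list(min_support = 0.015, min_confidence = 0.6,
                                min_lift = 1.0),
                  chord = list(min_support = 0.01, min_confidence = 0.6,
                               min_lift = 1.0)))
  }
  stopifnot(min_support >= 0, min_support <= 1,
            min_confidence >= 0, min_confidence <= 1, min_lift >= 0)
  list(min_support = min_support, min_confidence = min_confidence,
       min_lift = min_lift)
}

#' Build a post-by-term incidence matrix
#'
#' One row per post; one column per lexicon surface term observed at least
#' once in the corpus (drug and ADR terms partitioned). Presence is binary:
#' a term is marked present in a post iff [match_terms()] finds it at least
#' once — five mentions count the same as one.
#'
#' @param docs corpus tibble of cleaned posts, or a list of `token_doc`
#'   (token documents are matched on their re-joined token stream, so
#'   protected multi-word terms still match).
#' @param drug_lex `drug_lexicon`.
#' @param adr_lex `adr_lexicon`.
#' @return an `incidence_matrix`: list with `presence` (sparse logical
#'   Matrix, posts x terms), `post_ids`, `drug_terms`, `adr_terms`.
#' @export
build_incidence <- function(docs, drug_lex, adr_lex) {
  if (is.data.frame(docs)) {
    ids <- docs$id
    texts <- ifelse(is.na(docs$text), "", docs$text)
  } else if (is.list(docs) && all(vapply(docs, inherits, logical(1),
                                         "token_doc"))) {
    ids <- vapply(docs, function(d) d$post_id, character(1))
    texts <- vapply(docs, function(d) paste(d$tokens, collapse = " "),
                    character(1))
  } else {
    stop("docs must be a corpus tibble or a list of token_doc",
         call. = FALSE)
  }
  if (length(ids) == 0L) stop("empty corpus", call. = FALSE)
  d_terms <- surface_terms(drug_lex)
  a_terms <- setdiff(surface_terms(adr_lex), d_terms)
  hits_i <- integer(); hits_j <- integer()
  all_terms <- c(d_terms, a_terms)
  for (i in seq_along(texts)) {
    md <- match_terms(texts[i], drug_lex)
    ma <- match_terms(texts[i], adr_lex)
    found <- match(unique(c(md$surface_term, ma$surface_term)), all_terms)
    found <- found[!is.na(found)]
    hits_i <- c(hits_i, rep.int(i, length(found)))
    hits_j <- c(hits_j, found)
  }
  observed <- sort(unique(hits_j))
  presence <- Matrix::sparseMatrix(
    i = hits_i, j = match(hits_j, observed),
    dims = c(length(ids), length(observed)),
    dimnames = list(ids, all_terms[observed]))
  structure(list(presence = presence, post_ids = ids,
                 drug_terms = intersect(all_terms[observed], d_terms),
                 adr_terms = intersect(all_terms[observed], a_terms)),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix> ", length(x$post_ids), " post(s) x (",
      length(x$drug_terms), " drug + ", length(x$adr_terms),
      " ADR) term(s)\n", sep = "")
  invisible(x)
}

#' Mine drug-term to ADR-term association rules
#'
#' Evaluates every (drug term, ADR term) pair over the post-level incidence
#' and emits the rules passing all thresholds. For a rule d => a over
#' `n_total` posts with `n_ante` posts containing d, `n_cons` containing a
#' and `n_both` containing both:
#' support = n_both / n_total (the paper's "support"),
#' confidence = n_both / n_ante ("reliability"),
#' lift = confidence / (n_cons / n_total) ("improvement").
#' Pairs with `n_ante = 0` are skipped (confidence undefined). Rules are
#' sorted by descending lift, then descending support, then antecedent and
#' consequent lexicographically.
#'
#' @param m an `incidence_matrix`.
#' @param thresholds list from [rule_thresholds()].
#' @param direction `"drug_to_adr"` (default) or `"adr_to_drug"` — which
#'   side is the antecedent.
#' @return tibble of class `adr_rules` with columns `antecedent`,
#'   `consequent`, `n_both`, `n_ante`, `n_cons`, `n_total`, `support`,
#'   `confidence`, `lift`.
#' @export
mine_rules <- function(m, thresholds = rule_thresholds("strict"),
                       direction = c("drug_to_adr", "adr_to_drug")) {
  stopifnot(inherits(m, "incidence_matrix"))
  direction <- match.arg(direction)
  if (length(m$drug_terms) < 1L || length(m$adr_terms) < 1L) {
    stop("incidence matrix needs at least one drug and one ADR term",
         call. = FALSE)
  }
  n_total <- length(m$post_ids)
  D <- m$presence[, m$drug_terms, drop = FALSE] * 1
  A <- m$presence[, m$adr_terms, drop = FALSE] * 1
  n_drug <- Matrix::colSums(D)
  n_adr <- Matrix::colSums(A)
  both <- as.matrix(Matrix::crossprod(D, A))  # drug x adr co-mention counts
  if (direction == "drug_to_adr") {
    ante_terms <- m$drug_terms; cons_terms <- m$adr_terms
    n_ante <- n_drug; n_cons <- n_adr
  } else {
    ante_terms <- m$adr_terms; cons_terms <- m$drug_terms
    n_ante <- n_adr; n_cons <- n_drug
    both <- t(both)
  }
  grid <- expand.grid(a = seq_along(ante_terms), c = seq_along(cons_terms))
  n_both <- both[cbind(grid$a, grid$c)]
  na <- n_ante[grid$a]; nc <- n_cons[grid$c]
  keep <- na > 0
  rules <- tibble::tibble(
    antecedent = ante_terms[grid$a][keep],
    consequent = cons_terms[grid$c][keep],
    n_both = as.integer(n_both[keep]),
    n_ante = as.integer(na[keep]),
    n_cons = as.integer(nc[keep]),
    n_total = n_total)
  rules$support <- rules$n_both / rules$n_total
  rules$confidence <- rules$n_both / rules$n_ante
  rules$lift <- rules$confidence / (rules$n_cons / rules$n_total)
  rules <- rules[rules$support >= thresholds$min_support &
                   rules$confidence >= thresholds$min_confidence &
                   rules$lift >= thresholds$min_lift, ]
  rules <- rules[order(-rules$lift, -rules$support, rules$antecedent,
                       rules$consequent), ]
  class(rules) <- c("adr_rules", class(rules))
  rules
}

#' Chord-diagram co-occurrence matrix
#'
#' The drug-by-ADR count matrix behind a chord diagram: cell (d, a) holds
#' `n_both` for pairs surviving the thresholds used to mine `rules`, and 0
#' otherwise. Graphical rendering is out of scope; the matrix is exported
#' as data.
#'
#' @param m the `incidence_matrix` the rules were mined from.
#' @param rules `adr_rules` tibble.
#' @return integer matrix with drug rows and ADR columns.
#' @export
chord_matrix <- function(m, rules) {
  stopifnot(inherits(m, "incidence_matrix"))
  out <- matrix(0L, nrow = length(m$drug_terms),
                ncol = length(m$adr_terms),
                dimnames = list(m$drug_terms, m$adr_terms))
  if (nrow(rules)) {
    drug_side <- if (all(rules$antecedent %in% m$drug_terms)) {
      cbind(rules$antecedent, rules$consequent)
    } else {
      cbind(rules$consequent, rules$antecedent)
    }
    out[drug_side] <- rules$n_both
  }
  out
}

#' Write mined rules as CSV
#'
#' @param rules `adr_rules` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  utils::write.csv(as.data.frame(rules), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write the chord co-occurrence matrix as CSV
#'
#' @param mat matrix from [chord_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chord <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
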