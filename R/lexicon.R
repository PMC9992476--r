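#' Construct a drug lexicon
#'
#' A drug lexicon maps each active ingredient to the set of surface terms
#' (brand/product names plus the ingredient name itself) under which it is
#' mentioned in posts. Surface terms are normalized with [normalize_term()];
#' duplicates within an ingredient are collapsed, and surface terms shared
#' across ingredients are reported with a warning (they remain matchable but
#' resolve ambiguously).
#'
#' @param ingredient character vector, one element per surface term.
#' @param surface_term character vector of the same length.
#' @return an object of class `drug_lexicon`: a list with `entries`
#'   (named list ingredient -> character vector of normalized surface terms)
#'   and `normalization` (rule identifier).
#' @export
drug_lexicon <- function(ingredient, surface_term) {
  stopifnot(is.character(ingredient), is.character(surface_term),
            length(ingredient) == length(surface_term))
  if (length(ingredient) == 0L) {
    lex <- structure(list(entries = list(), normalization = "nfc-lower-ws"),
                     class = "drug_lexicon")
    return(lex)
  }
  ingredient <- normalize_term(ingredient)
  surface_term <- normalize_term(surface_term)
  if (any(!nzchar(surface_term)) || any(!nzchar(ingredient))) {
    stop("empty ingredient or surface term in drug lexicon", call. = FALSE)
  }
  entries <- lapply(split(surface_term, ingredient), unique)
  all_terms <- unlist(entries, use.names = FALSE)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup)) {
    warning("surface term(s) shared across ingredients: ",
            paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, normalization = "nfc-lower-ws"),
            class = "drug_lexicon")
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon> ", length(x$entries), " ingredient(s), ",
      length(surface_terms(x)), " surface term(s)\n", sep = "")
  invisible(x)
}

#' Construct an ADR lexicon
#'
#' Each entry ties a surface term (the form that appears in posts, possibly
#' a lay consumer expression) to a MedDRA-style Preferred Term (PT) and the
#' PT's System Organ Class (SOC). Within one lexicon every PT maps to exactly
#' one SOC; a PT carrying two SOCs is a consistency error because a wrong SOC
#' silently corrupts the downstream SOC profile. Duplicate normalized surface
#' forms are collapsed to the first occurrence with a warning.
#'
#' @param surface_term,preferred_term,soc,source character vectors of equal
#'   length; `source` is one of `"terminology_a"`, `"terminology_b"`,
#'   `"consumer"` (free tags are accepted but these three are canonical).
#' @return an object of class `adr_lexicon`: a tibble of entries with columns
#'   `surface_term` (normalized), `preferred_term`, `soc`, `source`, plus a
#'   `pt_soc` attribute (named character: PT -> SOC).
#' @export
adr_lexicon <- function(surface_term, preferred_term, soc,
                        source = "terminology_a") {
  stopifnot(is.character(surface_term), is.character(preferred_term),
            is.character(soc))
  n <- length(surface_term)
  stopifnot(length(preferred_term) == n, length(soc) == n)
  source <- rep_len(as.character(source), n)
  surface_term <- normalize_term(surface_term)
  if (n > 0 && (any(!nzchar(surface_term)) || any(!nzchar(preferred_term)) ||
                any(!nzchar(soc)))) {
    stop("empty surface term, preferred term or SOC in ADR lexicon",
         call. = FALSE)
  }
  entries <- tibble::tibble(surface_term = surface_term,
                            preferred_term = preferred_term,
                            soc = soc, source = source)
  # one SOC per PT, checked before any collapsing
  bad <- unique(entries[, c("preferred_term", "soc")])
  multi <- bad$preferred_term[duplicated(bad$preferred_term)]
  if (length(multi)) {
    labs <- vapply(unique(multi), function(pt) {
      paste0(pt, " -> {", paste(sort(unique(bad$soc[bad$preferred_term == pt])),
                                collapse = ", "), "}")
    }, character(1))
    stop("preferred term(s) mapped to multiple SOCs: ",
         paste(labs, collapse = "; "), call. = FALSE)
  }
  dup <- duplicated(entries$surface_term)
  if (any(dup)) {
    warning("duplicate normalized surface form(s) collapsed: ",
            paste(unique(entries$surface_term[dup]), collapse = ", "),
            call. = FALSE)
    entries <- entries[!dup, ]
  }
  pt_soc <- entries$soc[!duplicated(entries$preferred_term)]
  names(pt_soc) <- entries$preferred_term[!duplicated(entries$preferred_term)]
  structure(list(entries = entries, pt_soc = pt_soc), class = "adr_lexicon")
}

#' @export
print.adr_lexicon <- function(x, ...) {
  cat("<adr_lexicon> ", nrow(x$entries), " surface term(s), ",
      length(x$pt_soc), " preferred term(s), ",
      length(unique(x$entries$soc)), " SOC(s)\n", sep = "")
  invisible(x)
}

#' Construct a stop-word set
#'
#' @param words character vector of tokens (normalized internally).
#' @param provenance source tag per word (`"base"` or `"custom"`), recycled.
#' @return an object of class `stopword_set` with `words` (unique, normalized)
#'   and `provenance` aligned to `words`.
#' @export
stopword_set <- function(words = character(), provenance = "base") {
  stopifnot(is.character(words))
  provenance <- rep_len(as.character(provenance), length(words))
  words <- normalize_term(words)
  keep <- nzchar(words) & !duplicated(words)
  structure(list(words = words[keep], provenance = provenance[keep]),
            class = "stopword_set")
}

#' @export
print.stopword_set <- function(x, ...) {
  cat("<stopword_set> ", length(x$words), " word(s)\n", sep = "")
  invisible(x)
}

#' All surface terms of a lexicon
#'
#' @param lex a `drug_lexicon` or `adr_lexicon`.
#' @return character vector of normalized surface terms (unique).
#' @export
surface_terms <- function(lex) {
  if (inherits(lex, "drug_lexicon")) {
    unique(unlist(lex$entries, use.names = FALSE))
  } else if (inherits(lex, "adr_lexicon")) {
    lex$entries$surface_term
  } else {
    stop("not a lexicon", call. = FALSE)
  }
}

#' SOC of an ADR surface term
#'
#' @param lex an `adr_lexicon`.
#' @param surface surface form(s); normalized before lookup.
#' @return character vector of SOC labels; errors if any form is unknown.
#' @export
soc_of <- function(lex, surface) {
  stopifnot(inherits(lex, "adr_lexicon"))
  key <- normalize_term(surface)
  i <- match(key, lex$entries$surface_term)
  if (anyNA(i)) {
    stop("surface term(s) not in ADR lexicon: ",
         paste(key[is.na(i)], collapse = ", "), call. = FALSE)
  }
  lex$entries$soc[i]
}

#' Load a lexicon from disk
#'
#' Drug lexicons are TSV with columns `ingredient`, `surface_term`; ADR
#' lexicons are TSV with columns `surface_term`, `preferred_term`, `soc`,
#' `source`; stop-word files hold one token per line (UTF-8). All files have
#' a one-line header except stop-word lists.
#'
#' @param path file path.
#' @param kind one of `"drug"`, `"adr"`, `"stopword"`.
#' @return lexicon object of the matching class.
#' @export
load_lexicon <- function(path, kind = c("drug", "adr", "stopword")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (kind == "stopword") {
    words <- readLines(path, encoding = "UTF-8", warn = FALSE)
    return(stopword_set(words[nzchar(trimws(words))]))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  need <- switch(kind,
                 drug = c("ingredient", "surface_term"),
                 adr  = c("surface_term", "preferred_term", "soc", "source"))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(kind, " lexicon file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (kind == "drug") {
    drug_lexicon(tab$ingredient, tab$surface_term)
  } else {
    adr_lexicon(tab$surface_term, tab$preferred_term, tab$soc, tab$source)
  }
}

#' Write a lexicon to disk
#'
#' Inverse of [load_lexicon()]; TSV for drug/ADR lexicons, one word per line
#' for stop-word sets.
#'
#' @param lex lexicon object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  if (inherits(lex, "drug_lexicon")) {
    tab <- data.frame(
      ingredient = rep(names(lex$entries), lengths(lex$entries)),
      surface_term = unlist(lex$entries, use.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else if (inherits(lex, "adr_lexicon")) {
    utils::write.table(as.data.frame(lex$entries), path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else if (inherits(lex, "stopword_set")) {
    writeLines(lex$words, path, useBytes = TRUE)
  } else {
    stop("not a lexicon", call. = FALSE)
  }
  invisible(path)
}

#' Merge two ADR terminology sources on Preferred-Term keys
#'
#' Entries from the two sources that share a Preferred Term are unified: the
#' surface-term sets are unioned and every contributing source tag is kept.
#' The merged PT set is the union of the input PT sets. A PT carrying
#' different SOC labels in the two sources is a hard consistency error (both
#' labels are reported; there is no silent majority pick).
#'
#' @param a,b `adr_lexicon` objects (e.g. WHO-ART-style and SIDER-style
#'   sources already keyed to the same PT system).
#' @return merged `adr_lexicon`.
#' @export
merge_adr_sources <- function(a, b) {
  stopifnot(inherits(a, "adr_lexicon"), inherits(b, "adr_lexicon"))
  shared <- intersect(names(a$pt_soc), names(b$pt_soc))
  conflict <- shared[a$pt_soc[shared] != b$pt_soc[shared]]
  if (length(conflict)) {
    labs <- vapply(conflict, function(pt) {
      paste0(pt, ": '", a$pt_soc[[pt]], "' vs '", b$pt_soc[[pt]], "'")
    }, character(1))
    stop("SOC conflict across sources for preferred term(s): ",
         paste(labs, collapse = "; "), call. = FALSE)
  }
  both <- rbind(as.data.frame(a$entries), as.data.frame(b$entries))
  both <- both[order(both$preferred_term, both$surface_term, both$source), ]
  both <- both[!duplicated(both[, c("surface_term", "preferred_term",
                                    "source")]), ]
  # a surface form present under the same PT in both sources stays one entry;
  # adr_lexicon() collapses any residual duplicate surface forms with warning
  first <- !duplicated(both$surface_term)
  srcs <- vapply(split(both$source, both$surface_term), function(s) {
    paste(sort(unique(s)), collapse = "+")
  }, character(1))
  out <- both[first, ]
  out$source <- unname(srcs[out$surface_term])
  adr_lexicon(out$surface_term, out$preferred_term, out$soc, out$source)
}

#' Attach a consumer expression to an existing Preferred Term
#'
#' Consumer words are lay phrasings of a medical concept (e.g. a colloquial
#' phrase describing a skin eruption). They attach to a PT that must already
#' exist in the lexicon and inherit its SOC; their source tag is
#' `"consumer"`. Adding a surface form already present is a no-op with a
#' warning.
#'
#' @param lex an `adr_lexicon`.
#' @param surface new surface form.
#' @param preferred_term existing PT to attach to.
#' @return updated `adr_lexicon`.
#' @export
add_consumer_term <- function(lex, surface, preferred_term) {
  stopifnot(inherits(lex, "adr_lexicon"),
            is.character(surface), length(surface) == 1L,
            is.character(preferred_term), length(preferred_term) == 1L)
  if (!preferred_term %in% names(lex$pt_soc)) {
    stop("unknown preferred term: ", preferred_term, call. = FALSE)
  }
  key <- normalize_term(surface)
  if (key %in% lex$entries$surface_term) {
    warning("surface form already present, lexicon unchanged: ", key,
            call. = FALSE)
    return(lex)
  }
  e <- lex$entries
  adr_lexicon(c(e$surface_term, key),
              c(e$preferred_term, preferred_term),
              c(e$soc, unname(lex$pt_soc[[preferred_term]])),
              c(e$source, "consumer"))
}

#' Dictionary term matching with longest-first resolution
#'
#' Finds lexicon surface terms in a cleaned text by exact matching on the
#' normalized text, aligned to word boundaries. Candidate occurrences are
#' resolved longest-first with left-to-right tie-breaking at equal length,
#' so multi-word terms win over their prefixes ("Ketotop Gel" suppresses
#' "Ketotop" within its span) and the accepted spans are pairwise disjoint.
#' Multi-word terms match across single internal spaces (the normalization
#' guarantees there are never doubles).
#'
#' @param text a single character string (already cleaned; see
#'   [clean_text()]).
#' @param lex a `drug_lexicon` or `adr_lexicon`.
#' @return tibble with columns `surface_term`, `start`, `end` — 0-based
#'   half-open character offsets into the normalized text — ordered by
#'   `start`. Zero rows when nothing matches.
#' @export
match_terms <- function(text, lex) {
  stopifnot(is.character(text), length(text) == 1L)
  terms <- surface_terms(lex)
  if (length(terms) == 0L) stop("empty lexicon", call. = FALSE)
  norm <- normalize_term(text)
  empty <- tibble::tibble(surface_term = character(),
                          start = integer(), end = integer())
  if (!nzchar(norm)) return(empty)
  cand_term <- character(); cand_start <- integer(); cand_len <- integer()
  nc <- nchar(norm)
  for (tm in terms) {
    hits <- gregexpr(tm, norm, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    len <- nchar(tm)
    for (h in as.integer(hits)) {
      # word-boundary check: neighbors must not be alphanumeric
      before_ok <- h == 1L ||
        !grepl("[[:alnum:]]", substr(norm, h - 1L, h - 1L))
      after_ok <- h + len - 1L == nc ||
        !grepl("[[:alnum:]]", substr(norm, h + len, h + len))
      if (before_ok && after_ok) {
        cand_term <- c(cand_term, tm)
        cand_start <- c(cand_start, h)
        cand_len <- c(cand_len, len)
      }
    }
  }
  if (length(cand_term) == 0L) return(empty)
  ord <- order(-cand_len, cand_start)
  taken <- logical(nc)
  keep <- logical(length(ord))
  for (j in ord) {
    idx <- cand_start[j]:(cand_start[j] + cand_len[j] - 1L)
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      keep[j] <- TRUE
    }
  }
  res <- tibble::tibble(surface_term = cand_term[keep],
                        start = cand_start[keep] - 1L,
                        end = cand_start[keep] - 1L + cand_len[keep])
  res[order(res$start), ]
}
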