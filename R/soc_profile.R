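#' Aggregate detected ADR words into a System-Organ-Class profile
#'
#' Each detected surface term resolves through its Preferred Term to a SOC;
#' counts are summed per SOC and ranked (rank 1 = largest count, ties
#' broken lexicographically by SOC label so ranks are a full ordering).
#' The profile's total equals the total of the detected term counts.
#'
#' @param detected named integer vector, ADR surface term -> mention count
#'   (as returned by [detect_adr_words()]).
#' @param adr_lex `adr_lexicon` resolving every detected term.
#' @param source tag recorded on the profile (`"sns"` or `"external"`).
#' @return an object of class `soc_profile`: list with `counts` (named,
#'   sorted by rank), `ranks` (named integer) and `source`.
#' @export
build_soc_profile <- function(detected, adr_lex, source = "sns") {
  stopifnot(inherits(adr_lex, "adr_lexicon"))
  if (length(detected) == 0L) {
    return(structure(list(counts = stats::setNames(integer(), character()),
                          ranks = stats::setNames(integer(), character()),
                          source = source),
                     class = "soc_profile"))
  }
  stopifnot(!is.null(names(detected)), all(detected >= 0))
  socs <- soc_of(adr_lex, names(detected))  # errors on unresolvable terms
  counts <- vapply(split(as.integer(detected), socs), sum, integer(1))
  soc_profile(counts, source = source)
}

#' Construct a SOC profile from raw counts
#'
#' @param counts named non-negative integer vector, SOC label -> count.
#' @param source tag (`"sns"` or `"external"`).
#' @return a `soc_profile`.
#' @export
soc_profile <- function(counts, source = "external") {
  stopifnot(!is.null(names(counts)) || length(counts) == 0L,
            all(counts >= 0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  ranks <- stats::setNames(seq_along(counts), names(counts))
  structure(list(counts = counts, ranks = ranks, source = source),
            class = "soc_profile")
}

#' @export
print.soc_profile <- function(x, ...) {
  cat("<soc_profile> [", x$source, "] ", length(x$counts),
      " SOC(s), total ", sum(x$counts), "\n", sep = "")
  if (length(x$counts)) {
    top <- utils::head(x$counts, 5L)
    for (s in names(top)) cat(sprintf("  %2d. %-45s %d\n",
                                      x$ranks[[s]], s, top[[s]]))
  }
  invisible(x)
}

#' Read an external SOC count profile from CSV
#'
#' Column layout `soc,count` — the shape of a spontaneous-reporting-system
#' export aggregated to SOC level. The comparator is agnostic to whether
#' counts are reports or patients; it consumes whatever the CSV carries.
#'
#' @param path CSV path.
#' @param source tag recorded on the profile.
#' @return a `soc_profile`.
#' @export
read_soc_profile <- function(path, source = "external") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("soc", "count") %in% names(tab))) {
    stop("external profile CSV needs columns soc, count", call. = FALSE)
  }
  soc_profile(stats::setNames(tab$count, tab$soc), source = source)
}

#' Rank concordance between two SOC profiles
#'
#' Restricts both profiles to their shared SOC labels, re-ranks within the
#' intersection, and reports Spearman's rho on those ranks together with
#' the top-k overlap fraction `|top-k(p) ∩ top-k(q)| / k` (top-k taken
#' from each full profile) and a per-SOC rank table. With fewer than two
#' shared SOCs rho is undefined (`NA`) but the overlap is still computed.
#'
#' @param p,q `soc_profile` objects.
#' @param k size of the top set compared (default 5).
#' @return list of class `soc_concordance` with `rho`, `top_k_overlap`,
#'   `k`, `n_shared` and `rank_table` (tibble: soc, rank_p, rank_q over
#'   the intersection).
#' @export
compare_profiles <- function(p, q, k = 5L) {
  stopifnot(inherits(p, "soc_profile"), inherits(q, "soc_profile"), k >= 1)
  shared <- intersect(names(p$counts), names(q$counts))
  rank_table <- tibble::tibble(soc = character(), rank_p = integer(),
                               rank_q = integer())
  rho <- NA_real_
  if (length(shared) >= 1L) {
    # re-rank within the intersection; original tie-break order carries over
    rp <- rank(p$ranks[shared], ties.method = "first")
    rq <- rank(q$ranks[shared], ties.method = "first")
    rank_table <- tibble::tibble(soc = shared, rank_p = as.integer(rp),
                                 rank_q = as.integer(rq))
    rank_table <- rank_table[order(rank_table$rank_p), ]
    if (length(shared) >= 2L) {
      rho <- stats::cor(rp, rq, method = "spearman")
    }
  }
  top_p <- names(p$counts)[seq_len(min(k, length(p$counts)))]
  top_q <- names(q$counts)[seq_len(min(k, length(q$counts)))]
  overlap <- length(intersect(top_p, top_q)) / k
  structure(list(rho = rho, top_k_overlap = overlap, k = as.integer(k),
                 n_shared = length(shared), rank_table = rank_table),
            class = "soc_concordance")
}

#' @export
print.soc_concordance <- function(x, ...) {
  cat("<soc_concordance> rho = ",
      if (is.na(x$rho)) "undefined (<2 shared SOCs)" else
        formatC(x$rho, digits = 4, format = "f"),
      ", top-", x$k, " overlap = ", x$top_k_overlap,
      " (", x$n_shared, " shared SOC(s))\n", sep = "")
  invisible(x)
}

#' Serialize a concordance report to JSON
#'
#' @param x a `soc_concordance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(x, path) {
  stopifnot(inherits(x, "soc_concordance"))
  obj <- list(rho = if (is.na(x$rho)) "undefined" else x$rho,
              top_k_overlap = x$top_k_overlap, k = x$k,
              n_shared = x$n_shared,
              rank_table = as.data.frame(x$rank_table))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a detected-word count table as CSV
#'
#' @param detected named integer vector from [detect_adr_words()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detected <- function(detected, path) {
  tab <- data.frame(term = names(detected), count = as.integer(detected))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detected-word count table
#'
#' @param path CSV with columns `term`, `count`.
#' @return named integer vector.
#' @export
read_detected <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  stats::setNames(as.integer(tab$count), tab$term)
}
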