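Package: snsminer
Title: Adverse-Drug-Reaction Signal Detection from Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pharmacovigilance text-mining pipeline for social-media post
    corpora. Builds and merges tri-lexicons (drug terms, adverse-drug-reaction
    terms keyed by MedDRA-style preferred terms with System Organ Class
    mapping, and stop words), cleans and tokenizes posts with a pluggable
    analyzer, reduces a corpus to candidate ADR posts through a staged
    filtering cascade, mines drug-to-ADR association rules
    (support/confidence/lift) over post-level term incidence, trains
    skip-gram negative-sampling word embeddings to detect ADR words as
    lexicon-member neighbors of anchor terms, aggregates detections into a
    System-Organ-Class count profile, and compares that profile against an
    external spontaneous-reporting profile by rank concordance. Includes a
    synthetic-corpus generator with planted drug-ADR associations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
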