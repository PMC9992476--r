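test_that("drug lexicon loads the nine-term fixture with one ingredient", {
  lex <- demo_drug_lex()
  expect_s3_class(lex, "drug_lexicon")
  expect_length(lex$entries, 1L)
  expect_length(surface_terms(lex), 9L)
  expect_true("fastum gel" %in% surface_terms(lex))
})

test_that("loader validates schemas and collapses duplicate surface forms", {
  empty_stops <- withr::local_tempfile(lines = character())
  expect_length(load_lexicon(empty_stops, "stopword")$words, 0L)

  bad <- withr::local_tempfile(lines = c("ingredient\tname", "x\ty"))
  expect_error(load_lexicon(bad, "drug"), "surface_term")
  expect_error(load_lexicon(tempfile(), "adr"), "no such file")

  dup <- withr::local_tempfile(lines = c(
    "surface_term\tpreferred_term\tsoc\tsource",
    "rash\tRash\tSkin\tterminology_a",
    "Rash \tRash\tSkin\tterminology_b"))
  expect_warning(lex <- load_lexicon(dup, "adr"), "collapsed")
  expect_identical(nrow(lex$entries), 1L)

  conflict <- withr::local_tempfile(lines = c(
    "surface_term\tpreferred_term\tsoc\tsource",
    "rash\tRash\tSkin\tterminology_a",
    "rashes\tRash\tPsychiatric\tterminology_b"))
  expect_error(load_lexicon(conflict, "adr"), "Rash")
})

test_that("lexicons round-trip through their file formats", {
  lex <- demo_adr_lex()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  again <- load_lexicon(path, "adr")
  expect_identical(again$entries, lex$entries)

  stops <- stopword_set(c("so", "therefore"))
  spath <- withr::local_tempfile(fileext = ".txt")
  write_lexicon(stops, spath)
  expect_identical(load_lexicon(spath, "stopword")$words, stops$words)
})

test_that("ADR sources merge on preferred-term keys", {
  a <- adr_lexicon("itching", "Pruritus", "Skin and appendages disorders",
                   "terminology_a")
  b <- adr_lexicon("itchy", "Pruritus", "Skin and appendages disorders",
                   "terminology_b")
  m <- merge_adr_sources(a, b)
  expect_setequal(surface_terms(m), c("itching", "itchy"))
  expect_identical(names(m$pt_soc), "Pruritus")

  # idempotence and commutativity on conflict-free inputs
  x <- demo_adr_lex()
  expect_identical(merge_adr_sources(x, x)$entries[, c("surface_term",
                                                       "preferred_term",
                                                       "soc")],
                   x$entries[order(x$entries$preferred_term,
                                   x$entries$surface_term),
                             c("surface_term", "preferred_term", "soc")])
  ab <- merge_adr_sources(a, b)
  ba <- merge_adr_sources(b, a)
  expect_identical(ab$entries, ba$entries)

  b2 <- adr_lexicon("itchy", "Pruritus", "Psychiatric disorders",
                    "terminology_b")
  expect_error(merge_adr_sources(a, b2), "Skin.*Psychiatric")
})

test_that("consumer terms attach to existing PTs and inherit their SOC", {
  lex <- demo_adr_lex()
  n0 <- nrow(lex$entries)
  lex2 <- add_consumer_term(lex, "something comes up", "Rash")
  expect_identical(nrow(lex2$entries), n0 + 1L)
  expect_identical(soc_of(lex2, "something comes up"), soc_of(lex2, "rash"))
  expect_identical(
    lex2$entries$source[lex2$entries$surface_term == "something comes up"],
    "consumer")

  expect_warning(lex3 <- add_consumer_term(lex2, "Something Comes Up", "Rash"),
                 "already present")
  expect_identical(lex3$entries, lex2$entries)

  expect_error(add_consumer_term(lex, "weird feeling", "NotAPT"),
               "unknown preferred term")
})

test_that("dictionary matching is longest-first with disjoint spans", {
  dl <- demo_drug_lex()
  m <- match_terms("I tried Fastum Gel on my shoulder", dl)
  expect_identical(m$surface_term, "fastum gel")

  expect_identical(nrow(match_terms("", dl)), 0L)
  expect_identical(nrow(match_terms("nothing relevant here", dl)), 0L)

  # brute-force derived: both 'ketotop' and 'ketotop gel' occur as
  # substrings, longest-first keeps exactly the longer
  m2 <- match_terms("Ketotop Gel twice daily", dl)
  expect_identical(m2$surface_term, "ketotop gel")
  expect_identical(m2$start, 0L)
  expect_identical(m2$end, 11L)

  # matched spans are disjoint and substrings normalize to the reported term
  set.seed(11)
  terms <- surface_terms(dl)
  for (i in 1:25) {
    text <- paste(sample(c(terms, "filler", "words", "kneepain"),
                         8, replace = TRUE), collapse = " ")
    m <- match_terms(text, dl)
    if (nrow(m) < 1L) next
    norm <- normalize_term(text)
    expect_true(all(m$end > m$start))
    if (nrow(m) > 1L) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
    sub <- substring(norm, m$start + 1L, m$end)
    expect_identical(normalize_term(sub), m$surface_term)
  }
})
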