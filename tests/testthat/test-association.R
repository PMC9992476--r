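test_that("incidence is binary post-level presence", {
  lx <- rule_fixture_lexicons()
  one <- tibble::tibble(id = "s1", channel = "blog", date = NA_character_,
                        text = "ketoprofen rash")
  inc <- build_incidence(one, lx$drug, lx$adr)
  expect_identical(as.vector(as.matrix(inc$presence)), c(TRUE, TRUE))

  many <- tibble::tibble(id = "s1", channel = "blog", date = NA_character_,
                         text = paste(rep("ketoprofen", 5), collapse = " and "))
  inc2 <- build_incidence(many, lx$drug, lx$adr)
  expect_equal(sum(inc2$presence[, "ketoprofen"]), 1)

  three <- tibble::tibble(
    id = c("s1", "s2", "s3"), channel = "blog", date = NA_character_,
    text = c("ketoprofen rash", "rash only", "nothing"))
  inc3 <- build_incidence(three, lx$drug, lx$adr)
  expect_identical(
    unname(as.matrix(inc3$presence)),
    matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), nrow = 3))

  expect_error(build_incidence(three[0, ], lx$drug, lx$adr), "empty corpus")
})

test_that("the hand-worked 10-post corpus yields support 0.30, confidence 0.75, lift 2.5", {
  lx <- rule_fixture_lexicons()
  inc <- build_incidence(rule_fixture_posts(), lx$drug, lx$adr)
  rules <- mine_rules(inc, rule_thresholds("strict"))
  expect_identical(nrow(rules), 1L)
  expect_identical(rules$n_both, 3L)
  expect_identical(rules$n_ante, 4L)
  expect_identical(rules$n_cons, 3L)
  expect_equal(rules$support, 0.30)
  expect_equal(rules$confidence, 0.75)
  expect_equal(rules$lift, 2.5)
})

test_that("a single co-mention post gives the degenerate rule (1, 1, 1)", {
  lx <- rule_fixture_lexicons()
  one <- tibble::tibble(id = "s1", channel = "blog", date = NA_character_,
                        text = "ketoprofen rash")
  rules <- mine_rules(build_incidence(one, lx$drug, lx$adr))
  expect_equal(rules$support, 1)
  expect_equal(rules$confidence, 1)
  expect_equal(rules$lift, 1)
})

test_that("the strict profile excludes a rule with confidence 0.5", {
  # D in 4 of 10, A in 3 of 10, both in 2 -> confidence 0.5 < 0.6
  lx <- rule_fixture_lexicons()
  texts <- c("ketoprofen rash", "ketoprofen rash bg1", "ketoprofen bg2",
             "ketoprofen bg3", "rash bg4", "bg5", "bg6", "bg7", "bg8", "bg9")
  posts <- tibble::tibble(id = sprintf("q%02d", 1:10), channel = "blog",
                          date = NA_character_, text = texts)
  rules <- mine_rules(build_incidence(posts, lx$drug, lx$adr),
                      rule_thresholds("strict"))
  expect_identical(nrow(rules), 0L)
})

test_that("mining matches the brute-force oracle on random corpora", {
  set.seed(77)
  th <- rule_thresholds(NULL, min_support = 0.05, min_confidence = 0.3,
                        min_lift = 0.5)
  for (i in 1:40) {
    rc <- random_rule_corpus(sample(5:50, 1), sample(1:4, 1),
                             sample(1:6, 1))
    got <- mine_rules(build_incidence(rc$posts, rc$drug, rc$adr), th)
    got <- got[order(got$antecedent, got$consequent), ]
    want <- brute_force_rules(rc$posts, surface_terms(rc$drug),
                              surface_terms(rc$adr), th)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$antecedent, want$antecedent)
      expect_identical(got$consequent, want$consequent)
      expect_identical(got$n_both, want$n_both)
      expect_identical(got$n_ante, want$n_ante)
      expect_identical(got$n_cons, want$n_cons)
      expect_lt(max(abs(got$support - want$support)), 1e-12)
      expect_lt(max(abs(got$confidence - want$confidence)), 1e-12)
      expect_lt(max(abs(got$lift - want$lift)), 1e-12)
    }
  }
})

test_that("lift is 1 exactly at empirical independence and thresholds are anti-monotone", {
  lx <- rule_fixture_lexicons()
  # n_both * n_total = n_ante * n_cons: 2*8 = 4*4
  texts <- c("ketoprofen rash", "ketoprofen rash", "ketoprofen bg",
             "ketoprofen bg", "rash bg", "rash bg", "bg1", "bg2")
  posts <- tibble::tibble(id = sprintf("i%02d", 1:8), channel = "blog",
                          date = NA_character_, text = texts)
  inc <- build_incidence(posts, lx$drug, lx$adr)
  r <- mine_rules(inc, rule_thresholds(NULL, 0, 0, 0))
  expect_equal(r$lift, 1)

  set.seed(31)
  for (i in 1:10) {
    rc <- random_rule_corpus(30, 2, 3)
    inc <- build_incidence(rc$posts, rc$drug, rc$adr)
    loose <- mine_rules(inc, rule_thresholds(NULL, 0.01, 0.1, 0.2))
    tight <- mine_rules(inc, rule_thresholds(NULL, 0.05, 0.4, 0.9))
    key <- function(r) paste(r$antecedent, r$consequent)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("the chord matrix holds co-mention counts for surviving rules only", {
  lx <- rule_fixture_lexicons()
  inc <- build_incidence(rule_fixture_posts(), lx$drug, lx$adr)

  none <- mine_rules(inc, rule_thresholds(NULL, 0.99, 0.99, 10))
  expect_true(all(chord_matrix(inc, none) == 0L))

  rules <- mine_rules(inc, rule_thresholds("strict"))
  cm <- chord_matrix(inc, rules)
  expect_identical(dim(cm), c(1L, 1L))
  expect_identical(cm["ketoprofen", "rash"], 3L)
})

test_that("rules and chord matrices round-trip as CSV deterministically", {
  lx <- rule_fixture_lexicons()
  inc <- build_incidence(rule_fixture_posts(), lx$drug, lx$adr)
  rules <- mine_rules(inc)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, p1)
  write_rules(mine_rules(inc), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  back <- utils::read.csv(p1)
  expect_equal(back$lift, rules$lift)
})
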