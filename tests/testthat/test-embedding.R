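test_that("training rejects empty or degenerate corpora", {
  expect_error(train_sgns(list(), sgns_config()), "empty corpus")
  expect_error(train_sgns(list(c("only", "only", "only")),
                          sgns_config(min_count = 2L)),
               "fewer than 2 distinct")
})

test_that("the analytic pair gradient matches central finite differences", {
  set.seed(3)
  dim <- 12L; n <- 7L
  v <- stats::rnorm(dim)
  U <- matrix(stats::rnorm(n * dim), n, dim)
  labels <- c(1L, rep(0L, n - 1L))
  objective <- function(v, U) {
    z <- as.vector(U %*% v)
    sum(ifelse(labels == 1L, stats::plogis(z, log.p = TRUE),
               stats::plogis(-z, log.p = TRUE)))
  }
  g <- snsminer:::sgns_pair_grad_cpp(v, U, labels)
  eps <- 1e-6
  fd_v <- vapply(seq_len(dim), function(d) {
    vp <- v; vm <- v
    vp[d] <- vp[d] + eps; vm[d] <- vm[d] - eps
    (objective(vp, U) - objective(vm, U)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g$grad_v - fd_v)), 1e-5)
  fd_U <- U * 0
  for (i in seq_len(n)) {
    for (d in seq_len(dim)) {
      Up <- U; Um <- U
      Up[i, d] <- Up[i, d] + eps; Um[i, d] <- Um[i, d] - eps
      fd_U[i, d] <- (objective(v, Up) - objective(v, Um)) / (2 * eps)
    }
  }
  expect_lt(max(abs(g$grad_U - fd_U)), 1e-5)
})

test_that("training is deterministic for a fixed seed", {
  cc <- two_topic_corpus(17, n_docs = 40L, doc_len = 15L)
  cfg <- sgns_config(dim = 16L, window = 3L, epochs = 3L, seed = 99L)
  m1 <- train_sgns(cc$docs, cfg)
  m2 <- train_sgns(cc$docs, cfg)
  expect_identical(m1$input_vectors, m2$input_vectors)
  expect_identical(m1$output_vectors, m2$output_vectors)
  m3 <- train_sgns(cc$docs, sgns_config(dim = 16L, window = 3L,
                                        epochs = 3L, seed = 100L))
  expect_false(identical(m1$input_vectors, m3$input_vectors))
})

test_that("neighbor ranking follows hand-computed cosine order", {
  W <- rbind(a = c(1, 0), b = c(0.6, 0.8), c = c(-1, 0))
  m <- hand_model(W)
  nb <- neighbors(m, "a", k = 2L)
  expect_identical(nb$term, c("b", "c"))
  expect_equal(nb$similarity, c(0.6, -1))

  expect_identical(nrow(neighbors(m, "a", k = 0L)), 0L)
  expect_false("a" %in% neighbors(m, "a", k = 10L)$term)
  expect_error(neighbors(m, "zz", k = 1L), "not in vocabulary")

  # cosine bounds on trained vectors
  cc <- two_topic_corpus(23, n_docs = 40L, doc_len = 15L)
  mt <- train_sgns(cc$docs, sgns_config(dim = 16L, epochs = 3L, seed = 5L))
  nb2 <- neighbors(mt, "alpha01", k = nrow(mt$vocabulary))
  expect_true(all(abs(nb2$similarity) <= 1 + 1e-12))
})

test_that("topic neighborhoods are recovered across seeds", {
  fracs <- vapply(1:5, function(s) {
    cc <- two_topic_corpus(300 + s)
    m <- train_sgns(cc$docs, sgns_config(dim = 50L, window = 5L,
                                         epochs = 10L, seed = s))
    hits <- vapply(cc$topic1, function(w) {
      nb <- neighbors(m, w, k = nrow(m$vocabulary))
      nb <- nb$term[!(nb$term %in% cc$functionwords)]
      nb[1] %in% cc$topic1
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(mean(fracs), 0.9)
})

test_that("detection intersects anchor neighborhoods with the ADR lexicon", {
  adr <- demo_adr_lex()
  posts <- tibble::tibble(id = c("e1", "e2"), channel = "blog",
                          date = NA_character_,
                          text = c("rash and itching", "rash alone"))
  W <- rbind("ketoprofen" = c(1, 0), "fastum gel" = c(0.9, 0.1),
             "rash" = c(0.8, 0.6), "itching" = c(0.7, 0.7),
             "bgword" = c(-1, 0.2), "bgword2" = c(-1, 0.1))
  m <- hand_model(W)

  # neighborhood disjoint from the lexicon -> empty mapping
  none <- detect_adr_words(m, "bgword", adr, k = 1L, posts = posts)
  expect_length(none, 0L)

  det <- detect_adr_words(m, "ketoprofen", adr, k = 3L, posts = posts)
  expect_setequal(names(det), c("rash", "itching"))
  expect_identical(unname(det["rash"]), 2L)
  expect_identical(unname(det["itching"]), 1L)

  # two anchors with overlapping neighborhoods: union without double count
  det2 <- detect_adr_words(m, c("ketoprofen", "fastum gel"), adr, k = 3L,
                           posts = posts)
  expect_identical(det2, det)

  expect_error(detect_adr_words(m, "absent", adr, k = 2L, posts = posts),
               "no anchor")
})

test_that("a planted co-occurring ADR is detected with a plausible count", {
  cfg <- sim_config(n_posts = 1200L, ad_fraction = 0, duplicate_fraction = 0,
                    seed = 404L,
                    planted_pairs = list(list(
                      drug = "ketoprofen", adr = "rash", p_drug = 0.25,
                      p_adr_given_drug = 0.7, p_adr_background = 0.05)))
  g <- generate_corpus(cfg)
  dl <- drug_lexicon("ketoprofen", "ketoprofen")
  adr <- demo_adr_lex()
  posts <- clean_corpus(g$posts)
  docs <- tokenize_corpus(posts, protect = dl)
  m <- train_sgns(docs, sgns_config(dim = 50L, window = 5L, epochs = 6L,
                                    seed = 11L))
  drug_posts <- posts[g$truth$drug_ketoprofen, ]
  det <- detect_adr_words(m, "ketoprofen", adr, k = 25L, posts = drug_posts)
  expect_true("rash" %in% names(det))
  n_drug <- nrow(drug_posts)
  interval <- stats::qbinom(c(0.005, 0.995), n_drug, 0.7)
  expect_gte(det[["rash"]], interval[1])
  expect_lte(det[["rash"]], interval[2])
})

test_that("models round-trip through word2vec text format", {
  cc <- two_topic_corpus(29, n_docs = 30L, doc_len = 12L)
  m <- train_sgns(cc$docs, sgns_config(dim = 8L, epochs = 2L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".w2v")
  write_sgns_model(m, path)
  back <- read_sgns_model(path)
  expect_identical(rownames(back$input_vectors),
                   rownames(m$input_vectors))
  expect_equal(back$input_vectors, m$input_vectors, tolerance = 1e-12)
})
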