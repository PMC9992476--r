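#' Run the end-to-end ADR signal-detection pipeline
#'
#' Executes the stages in order — lexicon loading, preprocessing, the
#' filtering cascade, association-rule mining, embedding training, ADR
#' word detection, SOC-profile comparison — from a single configuration,
#' writing every artifact into an output directory together with a
#' manifest of paths and MD5 checksums. Reruns with an identical
#' configuration and seed reproduce identical checksums.
#'
#' The configuration is a named list (or YAML file path) with blocks:
#' \describe{
#'   \item{posts}{path to the JSONL corpus.}
#'   \item{drug_lexicon, adr_lexicon, stopwords}{lexicon file paths
#'     (stopwords optional).}
#'   \item{cascade}{optional list: `promo_tokens`, `max_urls`,
#'     `min_drug_mentions`, `min_adr_mentions`.}
#'   \item{profile}{rule-threshold profile name (default "strict").}
#'   \item{embedding}{optional list of [sgns_config()] arguments.}
#'   \item{anchors}{anchor terms for detection; default the drug surface
#'     terms plus the literal token "side effects".}
#'   \item{k}{neighbors per anchor (default 100).}
#'   \item{external_profile}{optional path to an external SOC CSV; when
#'     absent the concordance stage is skipped.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer seed propagated to every stochastic stage.}
#' }
#'
#' @param config named list or YAML file path.
#' @return the manifest: list with `stages` (per-stage status) and
#'   `artifacts` (named list of path + md5), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$posts),
            !is.null(config$drug_lexicon), !is.null(config$adr_lexicon),
            !is.null(config$out_dir))
  for (f in c(config$posts, config$drug_lexicon, config$adr_lexicon,
              config$stopwords, config$external_profile)) {
    if (!file.exists(f)) stop("configured file missing: ", f, call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- c("lexicon", "preprocess", "filter", "mine", "embed", "detect",
              "soc_compare")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  artifacts <- list()
  log_stage <- function(name, msg) {
    message(sprintf("[%s] %s", name, msg))
  }

  drug_lex <- load_lexicon(config$drug_lexicon, "drug")
  adr_lex <- load_lexicon(config$adr_lexicon, "adr")
  stops <- if (!is.null(config$stopwords)) {
    load_lexicon(config$stopwords, "stopword")
  } else stopword_set()
  status["lexicon"] <- "done"
  log_stage("lexicon", sprintf("%d drug terms, %d ADR terms, %d stop words",
                               length(surface_terms(drug_lex)),
                               nrow(adr_lex$entries), length(stops$words)))

  posts <- read_posts(config$posts)
  posts <- clean_corpus(posts)
  status["preprocess"] <- "done"
  log_stage("preprocess", sprintf("%d posts cleaned", nrow(posts)))

  cascade_cfg <- if (is.null(config$cascade)) list() else config$cascade
  cas <- run_cascade(posts, drug_lex, adr_lex, cascade_cfg)
  kept <- cas$posts
  report_path <- file.path(out_dir, "filter_report.json")
  write_filter_report(cas$report, report_path)
  kept_path <- file.path(out_dir, "kept.jsonl")
  write_posts(kept, kept_path)
  artifacts$filter_report <- report_path
  artifacts$kept_posts <- kept_path
  status["filter"] <- "done"
  log_stage("filter", paste(cas$report$stage_counts, collapse = " -> "))
  if (nrow(kept) == 0L) {
    stop("filter stage: no posts survive the cascade", call. = FALSE)
  }

  profile <- if (is.null(config$profile)) "strict" else config$profile
  inc <- build_incidence(kept, drug_lex, adr_lex)
  rules <- mine_rules(inc, rule_thresholds(profile))
  rules_path <- file.path(out_dir, "rules.csv")
  write_rules(rules, rules_path)
  chord_path <- file.path(out_dir, "chord.csv")
  write_chord(chord_matrix(inc, rules), chord_path)
  artifacts$rules <- rules_path
  artifacts$chord <- chord_path
  status["mine"] <- "done"
  log_stage("mine", sprintf("%d rule(s) pass the '%s' profile",
                            nrow(rules), profile))

  emb_args <- if (is.null(config$embedding)) list() else config$embedding
  emb_args$seed <- seed
  emb_cfg <- do.call(sgns_config, emb_args)
  docs <- tokenize_corpus(kept, protect = drug_lex, stops = stops)
  model <- train_sgns(docs, emb_cfg)
  model_path <- file.path(out_dir, "model.w2v")
  write_sgns_model(model, model_path)
  artifacts$model <- model_path
  status["embed"] <- "done"
  log_stage("embed", sprintf("vocabulary %d, dim %d",
                             nrow(model$vocabulary), emb_cfg$dim))

  anchors <- if (is.null(config$anchors)) {
    c(surface_terms(drug_lex), "side effects")
  } else config$anchors
  k <- if (is.null(config$k)) 100L else as.integer(config$k)
  detected <- withCallingHandlers(
    detect_adr_words(model, anchors, adr_lex, k = k, posts = kept),
    warning = function(w) {
      log_stage("detect", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  detected_path <- file.path(out_dir, "detected.csv")
  write_detected(detected, detected_path)
  artifacts$detected <- detected_path
  status["detect"] <- "done"
  log_stage("detect", sprintf("%d ADR word(s) detected", length(detected)))

  if (!is.null(config$external_profile)) {
    sns_prof <- build_soc_profile(detected, adr_lex, source = "sns")
    ext_prof <- read_soc_profile(config$external_profile)
    conc <- compare_profiles(sns_prof, ext_prof,
                             k = if (is.null(config$soc_k)) 5L
                                 else as.integer(config$soc_k))
    conc_path <- file.path(out_dir, "concordance.json")
    write_concordance(conc, conc_path)
    artifacts$concordance <- conc_path
    status["soc_compare"] <- "done"
    log_stage("soc_compare",
              sprintf("rho = %s, top-%d overlap = %.2f",
                      format(conc$rho), conc$k, conc$top_k_overlap))
  } else {
    status["soc_compare"] <- "skipped"
    log_stage("soc_compare", "no external profile configured; skipped")
  }

  manifest <- list(
    stages = as.list(status),
    seed = seed,
    artifacts = lapply(artifacts, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
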