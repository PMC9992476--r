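---
title: "Mining adverse-drug-reaction signals from social-media posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse-drug-reaction signals from social-media posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snsminer)
```

## The problem

Spontaneous-reporting systems (KAERS, FAERS and their peers) capture only a
fraction of the adverse drug reactions (ADRs) patients actually experience.
People do, however, talk about side effects on blogs and forums, in lay
language and without coding discipline. `snsminer` implements a pipeline
that turns such a post corpus into an ADR signal profile: posts are cleaned
and tokenized, reduced to candidate ADR posts by a staged filter, mined for
drug-term → ADR-term association rules, embedded with skip-gram negative
sampling (SGNS) so that additional ADR words can be found as neighbors of
anchor terms, and finally aggregated into a MedDRA-style System Organ Class
(SOC) count profile that can be compared against an external
spontaneous-reporting profile by rank concordance.

## The tri-lexicon

Three dictionaries drive everything:

* **Drug lexicon** — ingredient → surface terms (brand and product names
  plus the ingredient itself). Surface terms are what appear in text; the
  ingredient is the analysis unit.
* **ADR lexicon** — surface term → Preferred Term (PT) → SOC. Two
  terminology sources (in practice WHO-ART-style and SIDER-style exports,
  both keyed to MedDRA PTs) are merged on the PT key with
  `merge_adr_sources()`: surface sets are unioned and a PT carrying two
  different SOCs across sources is a hard error — a silently mis-assigned
  SOC would corrupt every downstream profile, so there is no majority vote.
  Lay "consumer" expressions attach to an existing PT with
  `add_consumer_term()` and inherit its SOC.
* **Stop words** — high-frequency, low-content tokens removed after
  tokenization.

The package ships only a small synthetic ADR lexicon
(`inst/extdata/adr_lexicon_synthetic.tsv`) mimicking the structure of the
licensed terminologies; it contains no WHO-ART, SIDER or MedDRA content.

All matching runs through one normalization rule (Unicode NFC, lowercase,
whitespace collapsed). Dictionary matching (`match_terms()`) is exact,
word-boundary-aligned, and resolves overlaps longest-first with
left-to-right tie-breaks, so a product name like "Ketotop Gel" suppresses
its prefix "Ketotop" inside the same span. We chose word-boundary-aligned
matching (rather than free substring matching) because drug names embedded
in longer alphanumeric strings are almost always false positives.

## Text preparation

`clean_text()` removes e-mail addresses, URLs, markup tags, control
characters and special symbols (defined as everything outside letters,
digits and space — the practical reading of an enumerated "special symbols"
rule), collapses space runs, and is idempotent. A `target-script-only`
policy additionally restricts the text to one Unicode script and drops lone
single-letter fragments (such as isolated Hangul jamo); tests run with
`keep-all` on ASCII fixtures because the script restriction is
corpus-specific, not pipeline-essential.

Tokenization is a pluggable contract: any `function(text)` returning either
a token vector or `(token, pos)` pairs can serve as the analyzer, which
keeps heavyweight morphological analyzers out of the dependency set while
allowing them in production. Drug names are replaced by atomic placeholders
before the analyzer runs and restored afterwards, so no analyzer can split
them; when the analyzer supplies part-of-speech tags only noun-tagged
tokens are kept (protected drug names are exempt from that filter).

## The filtering cascade

`run_cascade()` applies, in order: advertisement removal → drug-mention
requirement → ADR-mention requirement → duplicate removal, and reports
per-stage post counts (non-increasing by construction) plus the surviving
token count. Two choices deserve comment:

* **Ad detection** is a promo-token blacklist plus a pre-cleaning URL-count
  threshold, both configurable. Corpus-specific ad removal is never fully
  specified in field studies; a transparent, configurable heuristic is
  preferable to an opaque classifier here.
* **Duplicates** are exact matches of normalized text, collapsed to the
  earliest post by date (ties: smallest id). Fuzzy near-duplicate detection
  is deliberately out of the default path for reproducibility.

## Association rules

Over the surviving posts, `build_incidence()` builds a binary post × term
incidence matrix (presence, not counts — five mentions in one post equal
one), and `mine_rules()` evaluates every (drug term, ADR term) pair:

* support = n(both) / n(total)
* confidence = n(both) / n(antecedent) — the conditional frequency
* lift = confidence / (n(consequent) / n(total))

Because the rule space is the drug × ADR cross product, exhaustive
evaluation replaces Apriori-style itemset machinery; there are no
multi-item antecedents. Two threshold profiles ship: `"strict"`
(support ≥ 0.015, confidence ≥ 0.6, lift ≥ 1.0) for signal filtering and
`"chord"` (support ≥ 0.01, same otherwise) for co-occurrence export. The
chord-diagram export is the drug × ADR co-mention count matrix of the
surviving rules; rendering is left to any chord-plot tool.

Rules with an unobserved antecedent are skipped (confidence undefined),
never emitted as zeros.

## Embedding-based ADR word detection

`train_sgns()` is a from-scratch skip-gram negative-sampling trainer
(Rcpp): for center w and context c it maximizes
log σ(u_c·v_w) + Σ_k log σ(−u_k·v_w) with negatives from the 3/4-power
unigram distribution, a per-token context radius drawn uniformly from
[1, window], and linear learning-rate decay. Where the method leaves
hyper-parameters open we follow canonical word2vec defaults: 5 negatives,
initial rate 0.025, input vectors initialized uniformly in ±0.5/dim,
output vectors at zero. The study-scale profile is 300 dimensions with
window 10; the package default is 50 dimensions with window 5, which is
sufficient for corpora of a few thousand posts and keeps test runs fast.
Training is single-threaded with its own deterministic 64-bit generator,
so a fixed seed reproduces vectors bit-for-bit on any platform.

`detect_adr_words()` takes the union of the top-k cosine neighbors (input
vectors) of the configured anchors — by default the drug surface terms and
the literal token "side effects" — intersects it with the ADR lexicon's
surface forms, and counts, per detected term, the number of drug-filtered
posts mentioning it. k defaults to 100 and is deliberately generous: the
lexicon intersection is the precision filter.

## SOC profiles and external concordance

`build_soc_profile()` sums detected-term counts through the PT → SOC
mapping; ranks are positions in the count ordering with lexicographic
tie-breaks, so every SOC holds a distinct rank. `compare_profiles()`
restricts both profiles to their shared SOC labels, re-ranks within the
intersection, and reports Spearman's ρ plus the top-k overlap fraction
(default k = 5). "Followed a similar pattern" claims in the literature are
usually made by eye; ρ and top-k overlap are the two scale-free, rank-based
statistics that operationalize them. Shared-label restriction (not
zero-filled union) is the default because external registries report
different SOC inventories, and a zero-filled union would manufacture
agreement in the tail.

## The synthetic corpus generator

`generate_corpus()` emulates the data the pipeline is built for, with no
natural language: Zipf-distributed background tokens (exponent 1.1,
~Poisson(20) tokens per post), drug mentions at a configurable per-post
probability, planted ADR co-mentions (probability `p_adr_given_drug` in
drug posts, `p_adr_background` elsewhere), advertisement posts carrying a
promo token and a URL, and verbatim duplicate posts under fresh ids. The
planted pair used throughout the tests — p_drug = 0.2,
p_adr_given_drug = 0.7, p_adr_background = 0.05 — gives closed-form rule
metrics (support 0.14, confidence 0.7, lift ≈ 3.89 via
`expected_rule_metrics()`) that a 2,000-post corpus recovers within
sampling error; "null" corpora set `p_adr_given_drug = p_adr_background`
so that any strict-profile rule is a false positive.

Each planted pair also carries a small dedicated context vocabulary
(8 tokens) inserted around both the drug and the ADR token. This mirrors
how real posts work — drug talk and symptom talk share characteristic
vocabulary — and it is what makes the pair converge to one embedding
neighborhood: input-vector cosine similarity measures *shared contexts*
(second-order co-occurrence), and bare adjacency alone does not produce
it on a vocabulary this small. With `context_vocab_size = 0` the generator
plants pure adjacency, which the association miner still recovers but the
embedding detector generally will not; that contrast is itself informative
about what the embedding stage can and cannot see.

What the generator does **not** emulate: natural-language syntax, spelling
variation, code-switching, Korean morphology, temporal posting trends, and
topic drift. Passing tests therefore demonstrate the correctness of the
pipeline's logic under its stated model, not performance on real social
media.

## Numerical and reproducibility choices

* Problem sizes in the test-suite and in `scripts/acceptance.R` are chosen
  for quick desk runs: 2,000-post corpora for rule recovery, 500-post
  corpora across 20 seeds for the false-positive control, 200-document
  two-topic corpora at dimension 50 over 5 seeds for neighborhood
  recovery.
* The rule miner is exact integer counting; its oracle test demands exact
  count equality and 1e-12 metric agreement against brute-force
  enumeration.
* SGNS correctness is anchored by a gradient check (analytic vs. central
  finite differences, tolerance 1e-5) rather than by loss values, which
  are seed-dependent.
* All randomness flows from explicit seeds: R's RNG for the generator
  (restored on exit), a self-contained 64-bit LCG inside the C++ trainer.
* Degenerate inputs are first-class: empty corpora, empty stop-word sets,
  all-stop-word documents, k = 0 neighbor queries and <2 shared SOCs all
  have defined, tested behavior.

## Known limitations

* Dictionary matching is exact after normalization; misspellings and
  inflected forms are missed unless they are in the lexicon (consumer
  terms are the intended mechanism for that).
* Confidence/lift on cascade survivors is conditioned on posts containing
  both a drug and an ADR term; population-level metric recovery should be
  measured on the unfiltered corpus, as the tests do.
* The default regex tokenizer has no morphology; agglutinative languages
  need an external analyzer plugged into the tokenizer contract.
* Rank concordance treats the external profile as given; reporting biases
  of spontaneous systems are not modeled.
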