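# Hand-built fixtures shared across tests.

# Thesaurus with three networks: an acne-rosacea style network (one term
# contains the search string, the rest do not), a diabetes network, and an
# unrelated decoy network.
tiny_thesaurus <- function() {
  tibble::tribble(
    ~concept_id, ~chv_term,       ~descriptive_phrase, ~umls_term,
    "C1",        "acne rosacea",  "disorders rosacea", "rosacea",
    "C1",        "rosacea acne",  "rosacea acne",      "rosacea",
    "C2",        "diabetes",      "diabetes mellitus", "diabete",
    "C2",        "niddm",         "diabetes type ii",  "niddm",
    "C3",        "gout",          "gouty arthropathy", "podagra"
  )
}

tiny_lexica <- function() {
  tibble::tibble(
    disease_id = c("arthritis", "stroke", "heart_attack"),
    term = c("arthritis", "stroke", "heart attack")
  )
}

# A corpus spec used by several tests: two unambiguous planted rates.
small_corpus <- function(n = 2000, seed = 42,
                         fraction_english = 1, fraction_us = 1) {
  spec <- corpus_spec(
    n,
    mention_rate = c(arthritis = 0.08, stroke = 0.08, "heart attack" = 0.04),
    validity = c(arthritis = 0.9, stroke = 0.15, "heart attack" = 0.3),
    fraction_english = fraction_english,
    fraction_us_location = fraction_us,
    seed = seed
  )
  generate_corpus(spec, tiny_lexica())
}

# Build a judgment table directly from yes-counts for two raters.
judgments_from_counts <- function(term = "t", n = 30, yes_a, yes_b) {
  ids <- sprintf("tw%03d", seq_len(n))
  dplyr::bind_rows(
    tibble::tibble(term = term, tweet_id = ids, rater_id = "A",
                   judgment = rep(c("yes", "no"), c(yes_a, n - yes_a))),
    tibble::tibble(term = term, tweet_id = ids, rater_id = "B",
                   judgment = rep(c("yes", "no"), c(yes_b, n - yes_b)))
  )
}

# Judgment table from an explicit 2x2 contingency table of paired counts.
judgments_from_table <- function(yy, yn, ny, nn) {
  n <- yy + yn + ny + nn
  ids <- sprintf("tw%04d", seq_len(n))
  a <- rep(c("yes", "yes", "no", "no"), c(yy, yn, ny, nn))
  b <- rep(c("yes", "no", "yes", "no"), c(yy, yn, ny, nn))
  dplyr::bind_rows(
    tibble::tibble(term = "t", tweet_id = ids, rater_id = "A", judgment = a),
    tibble::tibble(term = "t", tweet_id = ids, rater_id = "B", judgment = b)
  )
}
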