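test_that("generated thesaurus networks contain search strings, permutations and compounds", {
  th <- generate_thesaurus(list(diabetes = "diabetes"), n_decoy_concepts = 0,
                           seed = 1)
  terms <- unique(unlist(th[c("chv_term", "descriptive_phrase", "umls_term")]))
  expect_true("diabetes" %in% terms)
  # compound: a superstring of the search string
  expect_true(any(terms != "diabetes" &
                    grepl("diabetes", terms, fixed = TRUE)))

  th2 <- generate_thesaurus(list(heart_attack = "heart attack"), seed = 1)
  terms2 <- unique(unlist(th2[c("chv_term", "descriptive_phrase", "umls_term")]))
  expect_true("attack heart" %in% terms2)
})

test_that("decoy concepts contain no search string and generation is deterministic", {
  dis <- list(acne = c("acne", "zit"), flu = "flu")
  a <- generate_thesaurus(dis, n_decoy_concepts = 5, seed = 99)
  b <- generate_thesaurus(dis, n_decoy_concepts = 5, seed = 99)
  expect_identical(a, b)
  decoy_terms <- unlist(a[startsWith(a$concept_id, "D"),
                          c("chv_term", "descriptive_phrase", "umls_term")])
  for (s in c("acne", "zit", "flu")) {
    expect_false(any(grepl(s, decoy_terms, fixed = TRUE)))
  }
  expect_error(generate_thesaurus(list()), class = "diseasetalk_input_error")
})

test_that("corpus generation plants no mentions when all rates are zero", {
  spec <- corpus_spec(100, mention_rate = c(arthritis = 0),
                      validity = c(arthritis = 0.5), seed = 3)
  corp <- generate_corpus(spec, tiny_lexica())
  expect_equal(nrow(corp$tweets), 100)
  expect_equal(nrow(corp$ground_truth), 0)
})

test_that("degenerate validity of 1 labels every mention medical", {
  spec <- corpus_spec(1000, mention_rate = c(arthritis = 0.5),
                      validity = c(arthritis = 1), seed = 4)
  corp <- generate_corpus(spec, tiny_lexica())
  expect_gt(nrow(corp$ground_truth), 0)
  expect_true(all(corp$ground_truth$is_medical))
})

test_that("planted validity and mention rates converge to their specification", {
  spec <- corpus_spec(20000, mention_rate = c(stroke = 0.1, arthritis = 0.1),
                      validity = c(stroke = 0.15, arthritis = 0.8), seed = 17)
  corp <- generate_corpus(spec, tiny_lexica())
  gt <- corp$ground_truth
  m <- sum(gt$term == "stroke")
  frac <- mean(gt$is_medical[gt$term == "stroke"])
  se <- sqrt(0.15 * 0.85 / m)
  expect_lt(abs(frac - 0.15), 3 * se)
  # empirical mention rate within 4 binomial SE of the spec rate
  for (t in c("stroke", "arthritis")) {
    rate <- sum(gt$term == t) / 20000
    expect_lt(abs(rate - 0.1), 4 * sqrt(0.1 * 0.9 / 20000))
  }
})

test_that("corpus generation is bit-reproducible and validates its inputs", {
  spec <- corpus_spec(500, mention_rate = c(arthritis = 0.1),
                      validity = c(arthritis = 0.5), fraction_english = 0.7,
                      fraction_us_location = 0.6, seed = 5)
  a <- generate_corpus(spec, tiny_lexica())
  b <- generate_corpus(spec, tiny_lexica())
  expect_identical(a, b)

  spec_bad <- corpus_spec(10, mention_rate = c(gout = 1),
                          validity = c(gout = 1), seed = 1)
  expect_error(generate_corpus(spec_bad, tiny_lexica()),
               class = "diseasetalk_input_error")
  expect_error(corpus_spec(10, mention_rate = c(a = 0.5),
                           validity = c(b = 1)),
               class = "diseasetalk_input_error")
  expect_error(corpus_spec(10, mention_rate = c(a = 1.5),
                           validity = c(a = 1)),
               class = "diseasetalk_input_error")
})

test_that("changing the rater seed does not perturb the corpus stream", {
  mk <- function(seed) {
    corpus_spec(300, mention_rate = c(arthritis = 0.2),
                validity = c(arthritis = 0.5), seed = seed)
  }
  corp <- generate_corpus(mk(8), tiny_lexica())
  pairs <- corp$ground_truth[, c("term", "tweet_id")]
  j1 <- simulate_raters(corp$ground_truth, pairs,
                        rater_spec(0.9, 0.9, seed = 1),
                        rater_spec(0.9, 0.9, seed = 2))
  corp2 <- generate_corpus(mk(8), tiny_lexica())
  expect_identical(corp$tweets, corp2$tweets)
  j2 <- simulate_raters(corp2$ground_truth, pairs,
                        rater_spec(0.9, 0.9, seed = 1),
                        rater_spec(0.9, 0.9, seed = 2))
  expect_identical(j1, j2)
})

test_that("perfect raters reproduce ground truth and agree with kappa 1", {
  corp <- small_corpus(n = 1000, seed = 21)
  pairs <- corp$ground_truth[, c("term", "tweet_id")]
  j <- simulate_raters(corp$ground_truth, pairs,
                       rater_spec(1, 1, seed = 1), rater_spec(1, 1, seed = 2))
  expect_equal(nrow(j), 2 * nrow(pairs))
  gt_key <- paste(corp$ground_truth$term, corp$ground_truth$tweet_id)
  truth <- corp$ground_truth$is_medical[match(paste(j$term, j$tweet_id), gt_key)]
  expect_identical(j$judgment == "yes", truth)
  expect_equal(cohens_kappa(j), 1)
})

test_that("coin-flip raters produce near-zero chance-corrected agreement", {
  corp <- small_corpus(n = 20000, seed = 31)
  pairs <- corp$ground_truth[, c("term", "tweet_id")]
  j <- simulate_raters(corp$ground_truth, pairs,
                       rater_spec(0.5, 0.5, seed = 11),
                       rater_spec(0.5, 0.5, seed = 12))
  # kappa has sd ~ 1/sqrt(n_pairs) under independence
  expect_lt(abs(cohens_kappa(j)), 4 / sqrt(nrow(pairs)))
})

test_that("rater simulation rejects pairs missing from ground truth", {
  corp <- small_corpus(n = 200, seed = 2)
  bad <- tibble::tibble(term = "arthritis", tweet_id = "not-a-tweet")
  expect_error(simulate_raters(corp$ground_truth, bad,
                               rater_spec(), rater_spec()),
               class = "diseasetalk_input_error")
})

test_that("co-mention probability plants a second distinct term", {
  spec <- corpus_spec(3000, mention_rate = c(arthritis = 0.3, stroke = 0.3),
                      validity = c(arthritis = 1, stroke = 1),
                      co_mention_prob = 0.5, seed = 13)
  corp <- generate_corpus(spec, tiny_lexica())
  per_tweet <- table(corp$ground_truth$tweet_id)
  expect_gt(sum(per_tweet == 2), 0)
  dup <- corp$ground_truth |>
    dplyr::count(tweet_id, term) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
})
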