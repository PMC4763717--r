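test_that("network retrieval returns the whole matched key-value network", {
  got <- retrieve_candidate_networks(tiny_thesaurus(), "acne")
  expect_setequal(got, c("acne rosacea", "disorders rosacea", "rosacea",
                         "rosacea acne"))
  expect_warning(none <- retrieve_candidate_networks(tiny_thesaurus(), "xyzzy"),
                 "no thesaurus network")
  expect_length(none, 0)
})

test_that("retrieval of two networks is their deduplicated union", {
  th <- tiny_thesaurus()
  # independent oracle: base-R union over the concept networks that contain
  # a matching element
  long <- data.frame(
    concept = rep(th$concept_id, 3),
    term = tolower(c(th$chv_term, th$descriptive_phrase, th$umls_term))
  )
  hits <- unique(long$concept[grepl("diabete", long$term, fixed = TRUE) |
                                grepl("gout", long$term, fixed = TRUE)])
  expected <- unique(long$term[long$concept %in% hits])
  got <- retrieve_candidate_networks(th, c("diabete", "gout"))
  expect_setequal(got, expected)
  expect_false(anyDuplicated(got) > 0)
})

test_that("decision files drop flagged terms and append declared plurals", {
  dec <- tibble::tibble(term = "depressed", pass = "grammatical",
                        action = "drop", plural_forms = NA)
  expect_equal(apply_decision_file(c("depressed", "depression"), dec),
               "depression")
  expect_equal(apply_decision_file(c("a", "b"), dec[0, ]), c("a", "b"))

  dec2 <- tibble::tibble(term = "migraine", pass = "grammatical",
                         action = "keep", plural_forms = "migraines")
  out <- apply_decision_file(c("migraine", "headache"), dec2)
  expect_equal(out, c("migraine", "migraines", "headache"))

  dec3 <- tibble::tibble(term = "nonesuch", pass = "medical", action = "drop",
                         plural_forms = NA)
  expect_error(apply_decision_file(c("a"), dec3), "nonesuch",
               class = "diseasetalk_input_error")
})

test_that("structural reduction drops compounds and reverse-order terms", {
  expect_equal(structural_reduce(c("asthma", "allergic asthma",
                                   "pollen asthma")),
               "asthma")
  # "hay fever" is the chv-term surface form, so it represents its
  # permutation class
  expect_equal(structural_reduce(c("hay fever", "fever hay"),
                                 prefer = "hay fever"),
               "hay fever")
  expect_equal(structural_reduce("diabetes"), "diabetes")
  # punctuation inside thesaurus constructions is stripped to whitespace
  # before tokenisation; "pain, back, radiating" is neither a compound of
  # nor a permutation of "back pain", so both survive in normalised form
  expect_equal(structural_reduce(c("back pain", "pain, back, radiating")),
               c("back pain", "pain back radiating"))
  # but a true permuted form is dropped
  expect_equal(structural_reduce(c("back pain", "pain, back"),
                                 prefer = "back pain"),
               "back pain")
})

test_that("permutation-class representative prefers the chv form, else lexicographic", {
  expect_equal(structural_reduce(c("fever hay", "hay fever"),
                                 prefer = "hay fever"),
               "hay fever")
  expect_equal(structural_reduce(c("fever hay", "hay fever")), "fever hay")
})

test_that("structural reduction is idempotent and subsequence-free on random inputs", {
  vocab <- c("heart", "attack", "acute", "chronic", "pain", "back", "hay",
             "fever", "asthma", "allergic")
  withr::with_seed(7, {
    for (rep in 1:25) {
      n <- sample(3:9, 1)
      cands <- unique(vapply(seq_len(n), function(i) {
        paste(sample(vocab, sample(1:3, 1)), collapse = " ")
      }, character(1)))
      once <- structural_reduce(cands)
      twice <- structural_reduce(once)
      expect_identical(twice, once)
      toks <- strsplit(once, " ", fixed = TRUE)
      for (i in seq_along(toks)) for (j in seq_along(toks)) {
        if (i == j) next
        pat <- paste0(" ", paste(toks[[j]], collapse = " "), " ")
        hay <- paste0(" ", paste(toks[[i]], collapse = " "), " ")
        expect_false(pat != hay && grepl(pat, hay, fixed = TRUE))
      }
    }
  })
})

test_that("lexicon building composes retrieval, decisions and reduction", {
  lex <- build_lexicon(tiny_thesaurus(), "diabetes", "diabete")
  expect_true("diabetes" %in% lex$term)
  expect_true(all(c("disease_id", "term") %in% names(lex)))
  expect_true(all(lex$disease_id == "diabetes"))

  expect_warning(empty <- build_lexicon(tiny_thesaurus()[0, ], "x", "y"),
                 "empty thesaurus")
  expect_equal(nrow(empty), 0)
})

test_that("a compound-and-permutation fixture reduces to the hand-derived list", {
  cands <- c("asthma", "allergic asthma", "asthma allergic", "pollen asthma",
             "hay fever", "fever hay", "niddm", "diabetes mellitus",
             "mellitus diabetes")
  # hand reduction: "asthma" absorbs its compounds and their permutations;
  # "hay fever" beats "fever hay" via chv preference; the two-word
  # diabetes forms are a permutation class with no one-word absorber
  got <- structural_reduce(cands, prefer = c("asthma", "hay fever",
                                             "diabetes mellitus"))
  expect_setequal(got, c("asthma", "hay fever", "niddm", "diabetes mellitus"))
})
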