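# Synthetic corpora with planted ground truth.
#
# Every downstream stage (filtering, matching, sampling, correction,
# correlation) is validated against corpora in which the true mention count
# and the true medical fraction of every term are known by construction.

# Fixed template banks. Non-medical templates mirror the observed ambiguity
# styles: metaphor, slang, homograph (astrological sign, name), URL fragment.
# Template vocabulary is covered by the bundled dictionary so English
# filtering behaves deterministically on synthetic tweets.
.templates_medical <- c(
  "my doctor says the {term} is getting worse",
  "just got diagnosed with {term} at the clinic",
  "grandma has been living with {term} for ten years",
  "the nurse explained how {term} affects the body",
  "taking new medication for my {term} every morning",
  "hospital visit confirmed it really is {term}",
  "raising awareness for {term} research this month",
  "my {term} symptoms flared up again last night"
)

.templates_nonmedical <- c(
  "that movie gave me a {term} of pure genius",
  "this new song is pure {term} i love it",
  "check out tinyurl dot com slash {term} for deals",
  "my horoscope says {term} season is coming",
  "nearly had a {term} when i saw the price",
  "the {term} emoji is trending again today",
  "named my cat {term} because why not",
  "playing {term} on the guitar all afternoon"
)

.templates_filler <- c(
  "good morning everyone have a lovely day",
  "cannot wait for the weekend to start",
  "watching the game with friends tonight",
  "coffee first then we can talk",
  "traffic on the highway is terrible again",
  "what a beautiful sunset over the lake",
  "reading a great book about old trains",
  "dinner was amazing thanks for the recipe"
)

# Tokens absent from the bundled dictionary; used for non-English tweets.
.gibberish_tokens <- c(
  "zxq", "vbnr", "qqch", "zzrt", "plkj", "mnbv", "xwyz",
  "qpfg", "hjkl", "bnmz", "qrtz", "vvpk", "zzal", "xxot"
)

.locations_us <- c(
  "Chicago, IL", "New York, NY", "Los Angeles", "Houston", "Philadelphia",
  "Phoenix", "San Antonio", "Seattle", "Denver", "Boston", "United States"
)

.locations_nonus <- c(
  "London", "Paris", "Toronto", "Sydney", "Berlin", "Tokyo",
  "somewhere on earth", ""
)

#' Specify a synthetic tweet corpus
#'
#' A `corpus_spec` fixes everything the generator needs: corpus size, the
#' per-tweet probability that each disease term is mentioned, the planted
#' validity of each term (the probability that a mention carries the medical
#' sense rather than a metaphorical, slang or homograph use), the fractions
#' of English-language and US-located tweets, and the seed.
#'
#' @param n_tweets Number of tweets to generate (>= 1).
#' @param mention_rate Named numeric vector: per-tweet mention probability for
#'   each term. Probabilities must sum to at most 1 because a tweet carries at
#'   most one planted term (plus an optional co-mention, see `co_mention_prob`).
#' @param validity Named numeric vector in `[0, 1]`: for each term with a
#'   mention rate, the probability that a planted mention is a true medical
#'   reference.
#' @param fraction_english Fraction of tweets written in (template) English.
#' @param fraction_us_location Fraction of tweets with an unambiguous US
#'   location string.
#' @param co_mention_prob Probability that a tweet with one planted mention
#'   also mentions a second, distinct term. The default 0 keeps planted
#'   mention counts exactly one per tweet.
#' @param seed Integer seed; all generator streams derive from it.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_tweets, mention_rate, validity,
                        fraction_english = 1, fraction_us_location = 1,
                        co_mention_prob = 0, seed = 1L) {
  if (length(n_tweets) != 1 || n_tweets < 1) {
    input_error("`n_tweets` must be a single integer >= 1")
  }
  if (length(mention_rate) && is.null(names(mention_rate))) {
    input_error("`mention_rate` must be a named numeric vector")
  }
  missing_validity <- setdiff(names(mention_rate), names(validity))
  if (length(missing_validity)) {
    input_error("terms with a mention rate but no planted validity: %s",
                paste(missing_validity, collapse = ", "))
  }
  probs <- c(mention_rate, validity, fraction_english, fraction_us_location,
             co_mention_prob)
  if (any(probs < 0 | probs > 1)) {
    input_error("all probabilities must lie in [0, 1]")
  }
  if (sum(mention_rate) > 1) {
    input_error("mention rates must sum to at most 1 (got %.3f)",
                sum(mention_rate))
  }
  structure(
    list(n_tweets = as.integer(n_tweets), mention_rate = mention_rate,
         validity = validity[names(mention_rate)],
         fraction_english = fraction_english,
         fraction_us_location = fraction_us_location,
         co_mention_prob = co_mention_prob, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Specify a simulated rater
#'
#' Stands in for a human annotator judging whether a sampled term mention
#' carries the medical sense. `sensitivity` is the probability of a Yes on a
#' truly medical mention; `specificity` the probability of a No on a
#' non-medical one. A perfect rater (both 1) reproduces ground truth.
#'
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @param seed Integer seed for this rater's judgment stream.
#' @return An object of class `rater_spec`.
#' @export
rater_spec <- function(sensitivity = 1, specificity = 1, seed = 1L) {
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1)) {
    input_error("sensitivity and specificity must lie in [0, 1]")
  }
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 seed = as.integer(seed)),
            class = "rater_spec")
}

#' Generate a thesaurus fixture in the consumer-health-vocabulary schema
#'
#' Emits a table of entries (concept_id, chv_term, descriptive_phrase,
#' umls_term) where entries sharing a concept_id form one key-value network.
#' Every disease gets a concept whose network contains a term matching one of
#' its search strings, one compound term (a superstring of a shorter term)
#' and one reverse-order term (tokens permuted), so structural vetting is
#' exercised. Decoy concepts contain no search string.
#'
#' @param diseases Named list: disease id -> character vector of search
#'   strings (1 to 7 each).
#' @param n_decoy_concepts Number of unrelated concepts to add.
#' @param seed Integer seed.
#' @return A tibble with columns concept_id, chv_term, descriptive_phrase,
#'   umls_term.
#' @export
generate_thesaurus <- function(diseases, n_decoy_concepts = 0, seed = 1L) {
  if (!length(diseases)) input_error("`diseases` must name at least one disease")
  if (is.null(names(diseases)) || any(!nzchar(names(diseases)))) {
    input_error("`diseases` must be a named list of search-string vectors")
  }
  if (n_decoy_concepts < 0) input_error("`n_decoy_concepts` must be >= 0")

  modifiers <- c("chronic", "acute", "severe", "recurrent", "mild")
  rows <- vector("list", length(diseases))
  withr::with_seed(substream_seed(seed, "thesaurus"), {
    for (i in seq_along(diseases)) {
      id <- names(diseases)[i]
      strings <- normalize_tokens(diseases[[i]])
      s1 <- strings[[1]]
      compound <- paste(sample(modifiers, 1), s1)
      toks <- tokenize(s1)[[1]]
      permuted <- if (length(toks) > 1) {
        paste(rev(toks), collapse = " ")
      } else {
        paste(rev(tokenize(compound)[[1]]), collapse = " ")
      }
      rows[[i]] <- tibble::tibble(
        concept_id = sprintf("C%04d", i),
        chv_term = s1,
        descriptive_phrase = compound,
        umls_term = permuted
      )
      # extra matching entry so networks have >1 row where more strings exist
      if (length(strings) > 1) {
        rows[[i]] <- dplyr::bind_rows(rows[[i]], tibble::tibble(
          concept_id = sprintf("C%04d", i),
          chv_term = strings[[2]],
          descriptive_phrase = paste(strings[[2]], "disorder nos"),
          umls_term = strings[[2]]
        ))
      }
    }
    decoy_vocab <- c("walnut", "lantern", "quartz", "meadow", "pigeon",
                     "anvil", "cobalt", "harbor", "saddle", "timber",
                     "velvet", "wicker", "gable", "mortar", "spindle")
    all_strings <- normalize_tokens(unlist(diseases))
    decoys <- vector("list", n_decoy_concepts)
    for (j in seq_len(n_decoy_concepts)) {
      repeat {
        w <- sample(decoy_vocab, 3)
        terms <- c(w[1], paste(w[1], w[2]), paste(w[3], w[1]))
        hit <- any(vapply(all_strings, function(s) {
          any(stringr::str_detect(terms, stringr::fixed(s)))
        }, logical(1)))
        if (!hit) break
      }
      decoys[[j]] <- tibble::tibble(
        concept_id = sprintf("D%04d", j),
        chv_term = terms[1], descriptive_phrase = terms[2],
        umls_term = terms[3]
      )
    }
  })
  dplyr::bind_rows(c(rows, decoys))
}

# Substitute terms into selected templates (vectorised).
.fill_template <- function(templates, idx, term) {
  stringr::str_replace(templates[idx], stringr::fixed("{term}"), term)
}

#' Generate a synthetic tweet corpus with planted ground truth
#'
#' Tweets are exchangeable; each carries at most one planted term mention
#' (two when `co_mention_prob > 0` fires). A planted mention inserts the term
#' verbatim once, inside a medical or non-medical template sentence according
#' to a Bernoulli draw with the term's planted validity. Non-English tweets
#' are built from out-of-dictionary tokens; locations are drawn from bundled
#' unambiguous US strings or non-US/ambiguous strings (a "London").
#'
#' @param spec A [corpus_spec()].
#' @param lexica A lexicon tibble (columns disease_id, term) as produced by
#'   [build_lexicon()]; every term with a mention rate must appear in it.
#' @return A list with `tweets` (tibble: id, text, location) and
#'   `ground_truth` (tibble: tweet_id, term, is_medical).
#' @export
generate_corpus <- function(spec, lexica) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (is.null(lexica) || !nrow(lexica)) input_error("`lexica` must be nonempty")
  unknown <- setdiff(names(spec$mention_rate), lexica$term)
  if (length(unknown)) {
    input_error("mention rate given for terms absent from all lexica: %s",
                paste(unknown, collapse = ", "))
  }

  n <- spec$n_tweets
  terms <- names(spec$mention_rate)
  ids <- sprintf("t%07d", seq_len(n))

  # Stream-split so each component has its own seeded stream.
  assign_term <- withr::with_seed(substream_seed(spec$seed, "mentions"), {
    if (length(terms)) {
      sample(c(terms, ".none"), n, replace = TRUE,
             prob = c(spec$mention_rate, 1 - sum(spec$mention_rate)))
    } else {
      rep(".none", n)
    }
  })
  second_term <- withr::with_seed(substream_seed(spec$seed, "comention"), {
    out <- rep(NA_character_, n)
    if (spec$co_mention_prob > 0 && length(terms) > 1) {
      fires <- assign_term != ".none" & runif(n) < spec$co_mention_prob
      out[fires] <- vapply(assign_term[fires], function(t) {
        sample(setdiff(terms, t), 1)
      }, character(1))
    }
    out
  })
  is_english <- withr::with_seed(substream_seed(spec$seed, "language"),
                                 runif(n) < spec$fraction_english)
  is_us <- withr::with_seed(substream_seed(spec$seed, "location"),
                            runif(n) < spec$fraction_us_location)
  location <- withr::with_seed(substream_seed(spec$seed, "location-pick"), {
    ifelse(is_us,
           sample(.locations_us, n, replace = TRUE),
           sample(.locations_nonus, n, replace = TRUE))
  })

  # Ground truth labels for planted mentions (primary + co-mention).
  gt1 <- tibble::tibble(tweet_id = ids, term = assign_term) |>
    dplyr::filter(.data$term != ".none")
  gt2 <- tibble::tibble(tweet_id = ids, term = second_term) |>
    dplyr::filter(!is.na(.data$term))
  ground_truth <- dplyr::bind_rows(gt1, gt2)
  ground_truth$is_medical <- withr::with_seed(
    substream_seed(spec$seed, "validity"),
    runif(nrow(ground_truth)) < spec$validity[ground_truth$term]
  )

  text <- withr::with_seed(substream_seed(spec$seed, "text"), {
    med_idx <- sample.int(length(.templates_medical), n, replace = TRUE)
    non_idx <- sample.int(length(.templates_nonmedical), n, replace = TRUE)
    fil_idx <- sample.int(length(.templates_filler), n, replace = TRUE)
    gib <- do.call(paste, as.data.frame(
      matrix(sample(.gibberish_tokens, 7L * n, replace = TRUE), nrow = n),
      optional = TRUE))

    has_mention <- assign_term != ".none"
    label1 <- ground_truth$is_medical[match(ids, gt1$tweet_id)]
    out <- .templates_filler[fil_idx]
    tmpl1 <- ifelse(label1, .templates_medical[med_idx],
                    .templates_nonmedical[non_idx])
    out[has_mention] <- .fill_template(tmpl1, has_mention,
                                       assign_term[has_mention])
    co <- which(!is.na(second_term))
    if (length(co)) {
      gt_key <- paste(ground_truth$term, ground_truth$tweet_id)
      lab2 <- ground_truth$is_medical[
        match(paste(second_term[co], ids[co]), gt_key)]
      tmpl2 <- ifelse(lab2, .templates_medical[med_idx[co]],
                      .templates_nonmedical[non_idx[co]])
      out[co] <- paste(out[co],
                       stringr::str_replace(tmpl2, stringr::fixed("{term}"),
                                            second_term[co]))
    }
    # non-English rewrites: gibberish, with any planted terms kept verbatim
    ne <- !is_english
    out[ne & !has_mention] <- gib[ne & !has_mention]
    i1 <- ne & has_mention
    out[i1] <- paste(gib[i1], assign_term[i1])
    i2 <- ne & !is.na(second_term)
    out[i2] <- paste(out[i2], second_term[i2])
    out
  })

  list(
    tweets = tibble::tibble(id = ids, text = text, location = location),
    ground_truth = ground_truth[order(ground_truth$tweet_id, ground_truth$term), ]
  )
}

#' Simulate two raters' Yes/No judgments on sampled term mentions
#'
#' Each sampled (term, tweet) pair receives one Yes/No judgment per rater,
#' drawn independently: a rater answers Yes with probability `sensitivity`
#' when the planted mention is medical and with probability
#' `1 - specificity` when it is not. The two raters use independent seeded
#' streams.
#'
#' @param ground_truth Ground-truth tibble from [generate_corpus()].
#' @param sample_pairs Tibble with columns term and tweet_id (a drawn
#'   appraisal sample); every pair must exist in the ground truth.
#' @param spec_a,spec_b [rater_spec()] objects for raters A and B.
#' @return A judgment tibble (term, tweet_id, rater_id, judgment) with two
#'   rows per sampled pair.
#' @export
simulate_raters <- function(ground_truth, sample_pairs, spec_a, spec_b) {
  stopifnot(inherits(spec_a, "rater_spec"), inherits(spec_b, "rater_spec"))
  key <- paste(sample_pairs$term, sample_pairs$tweet_id)
  gt_key <- paste(ground_truth$term, ground_truth$tweet_id)
  miss <- setdiff(key, gt_key)
  if (length(miss)) {
    input_error("sampled pairs missing from ground truth: %s",
                paste(head(miss, 5), collapse = "; "))
  }
  medical <- ground_truth$is_medical[match(key, gt_key)]
  judge <- function(spec, rater_id) {
    p_yes <- ifelse(medical, spec$sensitivity, 1 - spec$specificity)
    yes <- withr::with_seed(substream_seed(spec$seed, paste0("rater-", rater_id)),
                            runif(length(p_yes)) < p_yes)
    tibble::tibble(term = sample_pairs$term, tweet_id = sample_pairs$tweet_id,
                   rater_id = rater_id,
                   judgment = ifelse(yes, "yes", "no"))
  }
  dplyr::bind_rows(judge(spec_a, "A"), judge(spec_b, "B")) |>
    dplyr::arrange(.data$term, .data$tweet_id, .data$rater_id)
}
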