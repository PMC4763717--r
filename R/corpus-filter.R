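# Corpus filtering (English-language, US-location) and token-boundary term
# counting.

#' Read a word list (one word per line)
#'
#' @param path Path to a plain-text file, one lowercase word per line; lines
#'   starting with `#` are ignored.
#' @return Character vector of words.
#' @export
read_dictionary <- function(path) {
  words <- readr::read_lines(path)
  words <- stringr::str_to_lower(stringr::str_trim(words))
  words[nzchar(words) & !stringr::str_starts(words, stringr::fixed("#"))]
}

#' Read a location gazetteer
#'
#' Plain-text format: one place name per line; a line `[aliases]` starts the
#' country-alias section (default alias when absent: "united states").
#' Ambiguous city names (a "London", which exists both abroad and in Texas)
#' are simply left out of the file.
#'
#' @param path Path to the gazetteer file.
#' @return A list with character-vector elements `cities` and `aliases`.
#' @export
read_gazetteer <- function(path) {
  lines <- stringr::str_to_lower(stringr::str_trim(readr::read_lines(path)))
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, stringr::fixed("#"))]
  split_at <- match("[aliases]", lines)
  if (is.na(split_at)) {
    list(cities = lines, aliases = "united states")
  } else {
    list(cities = lines[seq_len(split_at - 1L)],
         aliases = lines[-seq_len(split_at)])
  }
}

#' Default bundled gazetteer
#' @return A gazetteer list (see [read_gazetteer()]).
#' @export
default_gazetteer <- function() {
  read_gazetteer(system.file("extdata", "gazetteer.txt",
                             package = "diseasetalk"))
}

#' Default bundled English word list
#'
#' A compact word list sufficient for the synthetic corpora and tests; real
#' analyses should supply a full English dictionary (e.g. a Hunspell word
#' list).
#' @return Character vector of words.
#' @export
default_dictionary <- function() {
  read_dictionary(system.file("extdata", "dictionary.txt",
                              package = "diseasetalk"))
}

# Strip URLs and sigils before language-ratio tokenisation. URLs are
# non-words; hashtags and mentions are ordinary tokens once the sigil goes.
.strip_nonlanguage <- function(text) {
  text <- stringr::str_replace_all(text, "(?i)\\bhttps?://\\S+|\\bwww\\.\\S+", " ")
  stringr::str_replace_all(text, "[#@]", " ")
}

#' English-language test by dictionary ratio
#'
#' A tweet counts as English when at least 50% of its alphabetic tokens are
#' found in the dictionary (boundary inclusive). Empty or URL-only texts are
#' not English.
#'
#' @param text Character vector of tweet texts.
#' @param dictionary Character vector of lowercase words.
#' @return Logical vector.
#' @export
is_english <- function(text, dictionary) {
  if (!length(dictionary)) input_error("dictionary must be nonempty")
  toks <- stringr::str_extract_all(
    stringr::str_to_lower(.strip_nonlanguage(text)), "[a-z]+")
  vapply(toks, function(tk) {
    length(tk) >= 1 && mean(tk %in% dictionary) >= 0.5
  }, logical(1))
}

#' US-location test against a gazetteer
#'
#' True when the case-folded location string contains a country alias
#' ("united states") as a substring, or when any comma-delimited segment or
#' whitespace token of it exactly equals an unambiguous US place name.
#' Ambiguous names are excluded from the gazetteer, so "London" is not US
#' even though a London, Texas exists.
#'
#' @param location Character vector of free-text location fields.
#' @param gaz Gazetteer list (see [read_gazetteer()]).
#' @return Logical vector.
#' @export
is_us <- function(location, gaz) {
  loc <- stringr::str_to_lower(location)
  loc[is.na(loc)] <- ""
  alias_hit <- if (length(gaz$aliases)) {
    Reduce(`|`, lapply(gaz$aliases, function(a) {
      stringr::str_detect(loc, stringr::fixed(a))
    }))
  } else {
    rep(FALSE, length(loc))
  }
  seg_hit <- vapply(loc, function(l) {
    if (!nzchar(l)) return(FALSE)
    segs <- stringr::str_squish(unlist(stringr::str_split(l, stringr::fixed(","))))
    toks <- unlist(stringr::str_split(stringr::str_squish(l), "[\\s,]+"))
    any(c(segs, toks) %in% gaz$cities)
  }, logical(1), USE.NAMES = FALSE)
  alias_hit | seg_hit
}

#' Read a JSON Lines tweet file
#'
#' One JSON object per line with keys id, text, location. Malformed lines
#' are skipped and counted.
#'
#' @param path Path to a JSONL file.
#' @return A list with `tweets` (tibble: id, text, location) and
#'   `n_malformed`.
#' @export
read_tweets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad <- vapply(parsed, function(p) {
    is.null(p) || !all(c("id", "text") %in% names(p))
  }, logical(1))
  if (any(bad)) {
    warn(sprintf("skipped %d malformed JSON line(s)", sum(bad)))
  }
  ok <- parsed[!bad]
  tweets <- tibble::tibble(
    id = vapply(ok, function(p) as.character(p$id), character(1)),
    text = vapply(ok, function(p) as.character(p$text), character(1)),
    location = vapply(ok, function(p) as.character(p$location %||% ""),
                      character(1))
  )
  list(tweets = tweets, n_malformed = sum(bad))
}

#' Write tweets as JSON Lines
#'
#' @param tweets Tibble with columns id, text, location.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    writeLines(jsonlite::toJSON(
      list(id = tweets$id[i], text = tweets$text[i],
           location = tweets$location[i]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Filter a corpus to English, US-located tweets
#'
#' Applies the dictionary-ratio English test, then the gazetteer US test.
#' Removal-only and order-preserving. The attrition report records the input
#' count, the per-filter rejection counts (location counted among
#' English-passing tweets) and the pass count.
#'
#' @param tweets Tibble (id, text, location) or path to a JSONL file.
#' @param dictionary Character vector of words (see [read_dictionary()]).
#' @param gaz Gazetteer list (see [read_gazetteer()]).
#' @return A list with `tweets` (the filtered tibble) and `report` (named
#'   list: n_input, n_malformed, n_not_english, n_not_us, n_pass).
#' @export
filter_corpus <- function(tweets, dictionary, gaz) {
  n_malformed <- 0L
  if (is.character(tweets) && length(tweets) == 1) {
    loaded <- read_tweets(tweets)
    tweets <- loaded$tweets
    n_malformed <- loaded$n_malformed
  }
  if (!nrow(tweets)) {
    return(list(tweets = tweets,
                report = list(n_input = 0L, n_malformed = n_malformed,
                              n_not_english = 0L, n_not_us = 0L, n_pass = 0L)))
  }
  eng <- is_english(tweets$text, dictionary)
  us <- is_us(tweets$location, gaz)
  keep <- eng & us
  list(
    tweets = tweets[keep, ],
    report = list(
      n_input = nrow(tweets),
      n_malformed = n_malformed,
      n_not_english = sum(!eng),
      n_not_us = sum(eng & !us),
      n_pass = sum(keep)
    )
  )
}

#' Count disease-term mentions at token boundaries
#'
#' A tweet is indexed once under every distinct (disease_id, term) whose
#' term occurs in the tweet text as a case-insensitive contiguous
#' token-boundary phrase. Repeated occurrences of one term inside one tweet
#' index once (the tweet is the annotation unit); a tweet containing terms
#' of two diseases is counted under both. The same surface term listed in
#' two lexica indexes under both disease ids.
#'
#' @param tweets Filtered tweet tibble (id, text).
#' @param lexica Lexicon tibble (disease_id, term).
#' @return The match index: a tibble (disease_id, term, tweet_id), one row
#'   per indexed pair.
#' @export
match_terms <- function(tweets, lexica) {
  if (is.null(lexica) || !nrow(lexica)) input_error("`lexica` must be nonempty")
  padded <- paste0(" ", normalize_tokens(tweets$text), " ")
  pairs <- dplyr::distinct(lexica, .data$disease_id, .data$term)
  uniq_terms <- unique(pairs$term)
  hits <- lapply(uniq_terms, function(t) {
    needle <- paste0(" ", normalize_tokens(t), " ")
    which(stringr::str_detect(padded, stringr::fixed(needle)))
  })
  names(hits) <- uniq_terms
  out <- purrr::pmap(pairs, function(disease_id, term) {
    idx <- hits[[term]]
    if (!length(idx)) return(NULL)
    tibble::tibble(disease_id = disease_id, term = term,
                   tweet_id = tweets$id[idx])
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble::tibble(disease_id = character(), term = character(),
                          tweet_id = character()))
  }
  res
}

#' Raw tweet counts per (disease, term)
#'
#' The raw tweet count (rcount) of a term is the number of distinct filtered
#' tweets containing it, before any ambiguity correction.
#'
#' @param index Match index from [match_terms()].
#' @param lexica Optional lexicon tibble; when given, terms with zero
#'   matches are included with rcount 0.
#' @return A tibble (disease_id, term, rcount).
#' @export
raw_counts <- function(index, lexica = NULL) {
  counts <- index |>
    dplyr::distinct(.data$disease_id, .data$term, .data$tweet_id) |>
    dplyr::count(.data$disease_id, .data$term, name = "rcount")
  if (!is.null(lexica)) {
    counts <- dplyr::distinct(lexica, .data$disease_id, .data$term) |>
      dplyr::left_join(counts, by = c("disease_id", "term")) |>
      dplyr::mutate(rcount = dplyr::coalesce(.data$rcount, 0L))
  }
  dplyr::arrange(counts, .data$disease_id, .data$term)
}
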