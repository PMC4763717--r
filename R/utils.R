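# Shared text normalisation and seeded-stream helpers.

#' Normalise a term or tweet text for token-boundary matching
#'
#' Case-folds, maps every non-alphanumeric character to a single space and
#' trims. Matching then reduces to fixed substring search on space-padded
#' strings, so a term matches only at token boundaries ("attack" does not
#' match "attacked").
#'
#' @param x Character vector.
#' @return Character vector of normalised token strings.
#' @keywords internal
normalize_tokens <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  stringr::str_squish(x)
}

# Tokenize a normalised string into its tokens.
tokenize <- function(x) {
  stringr::str_split(normalize_tokens(x), stringr::fixed(" "))
}

#' Derive a reproducible sub-stream seed
#'
#' Each pipeline stage draws from its own seeded stream so that, for example,
#' changing the rater seed never perturbs the generated corpus. Sub-seeds are
#' derived from a base seed and a stream label with a small multiplicative
#' hash, kept strictly below 2^31.
#'
#' @param seed Integer base seed.
#' @param stream Character stream label.
#' @return A single integer seed.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

# Stop with a classed input error (consistent condition class for callers).
input_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "diseasetalk_input_error")
}
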