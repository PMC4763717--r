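# Ambiguity correction: appraisal sampling, correction factors, validated
# counts, inter-rater agreement.
#
# The estimator: for each term, up to 30 mentions are sampled uniformly
# without replacement and judged Yes/No (medical sense?) by two raters. Each
# rater's Yes percentage is computed, the two are averaged into the term's
# correction factor c_t, and the validated count is
# vcount = rcount * c_t / 100, carried as a real number through every
# aggregation and rounded only for reporting.

#' Draw an appraisal sample for one term
#'
#' Uniform sample without replacement of `min(k, rcount)` tweet ids from the
#' term's match set; when the term occurs in `k` or fewer tweets, all of
#' them are taken. Reproducible under the seed.
#'
#' @param index Match index from [match_terms()].
#' @param term Term to sample.
#' @param disease_id Disease whose lexicon the term belongs to (a surface
#'   term may sit in several lexica; samples are drawn per pair).
#' @param k Maximum sample size (default 30).
#' @param seed Integer seed.
#' @return A tibble (disease_id, term, tweet_id); zero rows (with a warning)
#'   when the term matched no tweets.
#' @export
draw_sample <- function(index, term, disease_id, k = 30, seed = 1L) {
  if (!any(index$term == term & index$disease_id == disease_id)) {
    if (!any(index$term == term)) {
      input_error("term not present in the match index: %s", term)
    }
  }
  ids <- unique(index$tweet_id[index$term == term &
                                 index$disease_id == disease_id])
  if (!length(ids)) {
    warn(sprintf("term '%s' has raw count 0; empty sample", term))
    return(tibble::tibble(disease_id = character(), term = character(),
                          tweet_id = character()))
  }
  take <- min(k, length(ids))
  picked <- withr::with_seed(
    substream_seed(seed, paste("sample", disease_id, term)),
    sample(ids, take)
  )
  tibble::tibble(disease_id = disease_id, term = term, tweet_id = picked)
}

#' Draw appraisal samples for every (disease, term) pair in an index
#'
#' @param index Match index from [match_terms()].
#' @param k Maximum sample size per term (default 30).
#' @param seed Integer seed; each pair samples from its own derived stream,
#'   so adding a term does not perturb the others' samples.
#' @return A tibble (disease_id, term, tweet_id).
#' @export
draw_samples <- function(index, k = 30, seed = 1L) {
  pairs <- dplyr::distinct(index, .data$disease_id, .data$term)
  purrr::pmap(pairs, function(disease_id, term) {
    draw_sample(index, term, disease_id, k = k, seed = seed)
  }) |>
    dplyr::bind_rows()
}

#' Export an appraisal sample for human annotation
#'
#' Writes a CSV with the sampled tweets' text and one blank judgment column
#' per rater, ready to be filled in and read back with
#' [read_judgments()].
#'
#' @param sample Appraisal sample tibble (disease_id, term, tweet_id).
#' @param tweets Tweet tibble (id, text) used to look up the texts.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_sample <- function(sample, tweets, path) {
  out <- dplyr::left_join(sample, tweets[, c("id", "text")],
                          by = c(tweet_id = "id"))
  out$judgment_rater_A <- ""
  out$judgment_rater_B <- ""
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a judgment table
#'
#' Schema (term, tweet_id, rater_id, judgment) with judgment in yes/no —
#' the same schema [simulate_raters()] produces, so human and simulated
#' judgments are interchangeable.
#'
#' @param path CSV path.
#' @return A judgment tibble.
#' @export
read_judgments <- function(path) {
  j <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("term", "tweet_id", "rater_id", "judgment")
  miss <- setdiff(need, names(j))
  if (length(miss)) {
    input_error("judgment file is missing columns: %s",
                paste(miss, collapse = ", "))
  }
  j$judgment <- stringr::str_to_lower(j$judgment)
  bad <- setdiff(unique(j$judgment), c("yes", "no"))
  if (length(bad)) input_error("judgments must be yes/no; found: %s",
                               paste(bad, collapse = ", "))
  j
}

# Validate that every sampled (term, tweet_id) has exactly one row per rater.
.check_complete <- function(judgments) {
  counts <- judgments |>
    dplyr::count(.data$term, .data$tweet_id, .data$rater_id)
  if (any(counts$n != 1)) {
    input_error("duplicate judgments for some (term, tweet, rater) triples")
  }
  wide <- counts |>
    dplyr::count(.data$term, .data$tweet_id, name = "n_raters")
  gaps <- wide[wide$n_raters != 2, ]
  if (nrow(gaps)) {
    input_error("missing rater judgments for: %s",
                paste(paste(gaps$term, gaps$tweet_id), collapse = "; "))
  }
  invisible(TRUE)
}

#' Correction factor and validated count for one term
#'
#' Each rater's Yes percentage over the sample is computed; the correction
#' factor c_t is their mean; the validated count is rcount * c_t / 100,
#' kept as a real number.
#'
#' @param judgments Judgment tibble covering the term (two raters per
#'   sampled tweet).
#' @param term Term to score.
#' @param rcount The term's raw tweet count.
#' @return A one-row tibble (term, n_sampled, p_rater_A, p_rater_B,
#'   correction_factor, rcount, vcount).
#' @export
term_correction <- function(judgments, term, rcount) {
  j <- judgments[judgments$term == term, ]
  if (!nrow(j)) input_error("no judgments for term: %s", term)
  .check_complete(j)
  per_rater <- j |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::summarise(p = 100 * mean(.data$judgment == "yes"),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$rater_id)
  if (nrow(per_rater) != 2) {
    input_error("expected exactly 2 raters for term %s, found %d",
                term, nrow(per_rater))
  }
  c_t <- mean(per_rater$p)
  tibble::tibble(
    term = term, n_sampled = per_rater$n[1],
    p_rater_A = per_rater$p[1], p_rater_B = per_rater$p[2],
    correction_factor = c_t, rcount = rcount,
    vcount = rcount * c_t / 100
  )
}

#' Correction factors for every term in a judgment table
#'
#' @param judgments Judgment tibble (possibly many terms).
#' @param counts Raw-count tibble (disease_id, term, rcount) from
#'   [raw_counts()].
#' @return A tibble with one row per (disease_id, term).
#' @export
term_corrections <- function(judgments, counts) {
  missing <- setdiff(unique(judgments$term), counts$term)
  if (length(missing)) {
    input_error("judged terms missing from the count table: %s",
                paste(missing, collapse = ", "))
  }
  purrr::pmap(counts, function(disease_id, term, rcount, ...) {
    if (!any(judgments$term == term)) {
      if (rcount == 0) {
        return(tibble::tibble(disease_id = disease_id, term = term,
                              n_sampled = 0L, p_rater_A = NA_real_,
                              p_rater_B = NA_real_,
                              correction_factor = NA_real_,
                              rcount = rcount, vcount = 0))
      }
      input_error("no judgments for term with nonzero count: %s", term)
    }
    dplyr::bind_cols(tibble::tibble(disease_id = disease_id),
                     term_correction(judgments, term, rcount))
  }) |>
    dplyr::bind_rows()
}

#' Lexicon-level correction: validated count per disease
#'
#' Term-level raw and validated counts are summed over a disease's lexicon;
#' the lexicon's weighted percentage is 100 * vcount / rcount (the
#' term-level factors weighted by term frequency). Flagged `NA` when the
#' lexicon matched nothing.
#'
#' @param corrections Term-correction tibble from [term_corrections()].
#' @return A tibble (disease_id, rcount, vcount, weighted_percent,
#'   pooled_yes, pooled_n); `pooled_*` give the two-rater pooled instance
#'   fraction (2 * vcount out of 2 * rcount) used in reporting.
#' @export
lexicon_correction <- function(corrections) {
  corrections |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::summarise(rcount = sum(.data$rcount), vcount = sum(.data$vcount),
                     .groups = "drop") |>
    dplyr::mutate(
      weighted_percent = dplyr::if_else(.data$rcount > 0,
                                        100 * .data$vcount / .data$rcount,
                                        NA_real_),
      pooled_yes = 2 * .data$vcount,
      pooled_n = 2 * .data$rcount
    )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement over the paired Yes/No judgments:
#' kappa = (p_o - p_e) / (1 - p_e), with p_o the observed agreement and
#' p_e the product-of-marginals chance agreement. Returns 1 for perfect
#' agreement even when chance agreement is 1 (both raters constant and
#' identical).
#'
#' @param judgments Judgment tibble with raters A and B.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(judgments) {
  .check_complete(judgments)
  wide <- judgments |>
    tidyr::pivot_wider(id_cols = c("term", "tweet_id"),
                       names_from = "rater_id", values_from = "judgment")
  if (!all(c("A", "B") %in% names(wide))) {
    input_error("kappa requires raters labelled A and B")
  }
  n <- nrow(wide)
  p_o <- mean(wide$A == wide$B)
  p_e <- sum(vapply(c("yes", "no"), function(cat) {
    mean(wide$A == cat) * mean(wide$B == cat)
  }, numeric(1)))
  if (p_e == 1) return(if (p_o == 1) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}
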