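# Disease lexicon construction from a CHV-schema thesaurus.
#
# Three passes: key-value network retrieval by search string, a declarative
# vetting decision file (the mechanised form of the grammatical and medical
# review), and structural reduction of compound and reverse-order terms.

#' Read a thesaurus table
#'
#' Expects the consumer-health-vocabulary style schema: one entry per row
#' with columns concept_id, chv_term, descriptive_phrase, umls_term. Entries
#' sharing a concept_id form one key-value network of associated terms.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the four schema columns.
#' @export
read_thesaurus <- function(path) {
  th <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("concept_id", "chv_term", "descriptive_phrase", "umls_term")
  miss <- setdiff(need, names(th))
  if (length(miss)) {
    input_error("thesaurus is missing columns: %s", paste(miss, collapse = ", "))
  }
  th[need]
}

#' Retrieve candidate terms by key-value network expansion
#'
#' A concept's entire network of terms becomes candidate material whenever
#' any one of its term elements contains any search string as a
#' case-insensitive substring. The union over all matched networks is
#' returned, case-folded and deduplicated, in first-appearance order. This
#' retrieval is deliberately inclusive; vetting happens downstream.
#'
#' @param thesaurus Thesaurus tibble (see [read_thesaurus()]).
#' @param search_strings Character vector of search strings (1 to 7 is the
#'   typical range; more or fewer draws a warning, not an error).
#' @return Character vector of candidate terms (lowercase).
#' @export
retrieve_candidate_networks <- function(thesaurus, search_strings) {
  if (!nrow(thesaurus)) input_error("thesaurus is empty")
  if (!length(search_strings) || length(search_strings) > 7) {
    warn(sprintf("unusual number of search strings (%d); typical range is 1-7",
                 length(search_strings)))
  }
  long <- tidyr::pivot_longer(
    thesaurus, c("chv_term", "descriptive_phrase", "umls_term"),
    names_to = "slot", values_to = "term")
  long$term <- stringr::str_to_lower(long$term)
  strings <- stringr::str_to_lower(search_strings)

  hit <- Reduce(`|`, lapply(strings, function(s) {
    stringr::str_detect(long$term, stringr::fixed(s))
  }))
  matched_concepts <- unique(long$concept_id[hit & !is.na(hit)])
  if (!length(matched_concepts)) {
    warn("no thesaurus network matched any search string")
    return(character(0))
  }
  terms <- long$term[long$concept_id %in% matched_concepts]
  unique(terms[nzchar(terms)])
}

#' Read a vetting decision file
#'
#' The decision file is the reproducible record of the manual grammatical
#' (noun-form) and medical (does the term denote the disease?) review.
#' Columns: term, pass (grammatical | medical), action (keep | drop),
#' plural_forms (pipe-separated additions, may be empty).
#'
#' @param path Path to a CSV file.
#' @return A decision tibble.
#' @export
read_decision_file <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("term", "pass", "action")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    input_error("decision file is missing columns: %s",
                paste(miss, collapse = ", "))
  }
  if (!"plural_forms" %in% names(d)) d$plural_forms <- NA_character_
  bad <- setdiff(unique(d$action), c("keep", "drop"))
  if (length(bad)) input_error("unknown decision action: %s", paste(bad, collapse = ", "))
  d
}

#' Apply a vetting decision file to candidate terms
#'
#' Drops terms flagged `drop`, appends any declared plural forms directly
#' after their base term, and leaves everything else untouched
#' (order-stable). A decision naming a term that is not among the candidates
#' is an error: it indicates a stale decision file.
#'
#' @param candidates Character vector of candidate terms.
#' @param decisions Decision tibble (see [read_decision_file()]); may have
#'   zero rows.
#' @return Character vector of vetted terms.
#' @export
apply_decision_file <- function(candidates, decisions) {
  if (is.null(decisions) || !nrow(decisions)) return(candidates)
  decisions$term <- stringr::str_to_lower(decisions$term)
  unknown <- setdiff(decisions$term, candidates)
  if (length(unknown)) {
    input_error("decision file references unknown term(s): %s",
                paste(unknown, collapse = ", "))
  }
  drop <- decisions$term[decisions$action == "drop"]
  plurals <- decisions[!is.na(decisions$plural_forms) &
                         nzchar(decisions$plural_forms) &
                         decisions$action != "drop", ]
  out <- list()
  for (term in setdiff(candidates, drop)) {
    out[[length(out) + 1L]] <- term
    extra <- plurals$plural_forms[plurals$term == term]
    if (length(extra)) {
      out[[length(out) + 1L]] <- stringr::str_to_lower(
        unlist(stringr::str_split(extra, stringr::fixed("|"))))
    }
  }
  unique(unlist(out) %||% character(0))
}

#' Structurally reduce a candidate term list
#'
#' Two reductions, reflecting how token-boundary matching behaves in a
#' corpus: (a) compound terms — any multi-word candidate whose token sequence
#' contains a retained candidate as a contiguous subsequence is dropped,
#' because the shorter term already retrieves every tweet the longer one
#' would ("asthma" subsumes "allergic asthma"); (b) reverse-order terms —
#' thesaurus constructions like "fever hay" that are a token permutation of a
#' retained candidate are dropped. Within a permutation class the retained
#' representative is the form occurring in `prefer` (typically the chv_term
#' column), else the lexicographically first. Single-word terms are never
#' dropped.
#'
#' @param candidates Character vector of candidate terms.
#' @param prefer Character vector of preferred surface forms used to break
#'   permutation-class ties (default none).
#' @return Reduced character vector; idempotent.
#' @export
structural_reduce <- function(candidates, prefer = character(0)) {
  if (!length(candidates)) return(character(0))
  norm <- normalize_tokens(candidates)
  keepers <- !duplicated(norm) & nzchar(norm)
  cand <- norm[keepers]
  toks <- tokenize(cand)
  nt <- lengths(toks)

  contains_sub <- function(long, short) {
    nl <- length(long); ns <- length(short)
    if (ns >= nl) return(FALSE)
    for (s in seq_len(nl - ns + 1L)) {
      if (all(long[s:(s + ns - 1L)] == short)) return(TRUE)
    }
    FALSE
  }

  # compound pass: process by increasing token count so containment is
  # always checked against already-retained shorter terms
  ord <- order(nt, cand)
  retained <- logical(length(cand))
  for (i in ord) {
    hit <- FALSE
    if (nt[i] > 1) {
      for (j in which(retained)) {
        if (contains_sub(toks[[i]], toks[[j]])) { hit <- TRUE; break }
      }
    }
    retained[i] <- !hit
  }

  # reverse-order pass: one representative per token-multiset class
  surv <- which(retained)
  class_key <- vapply(surv, function(i) {
    paste(sort(toks[[i]]), collapse = " ")
  }, character(1))
  prefer <- normalize_tokens(prefer)
  rep_of <- tapply(surv, class_key, function(members) {
    if (length(members) == 1) return(members)
    pref <- members[cand[members] %in% prefer]
    if (length(pref)) pref[1] else members[order(cand[members])][1]
  })
  keep_idx <- sort(unlist(rep_of))
  # return the normalised (lowercase, punctuation-stripped) surface forms:
  # these are the forms the corpus matcher operates on
  cand[keep_idx]
}

#' Build one disease lexicon
#'
#' Composes the three vetting passes: network retrieval, decision-file
#' application, structural reduction. Returns a tidy lexicon: one row per
#' retained lowercase term.
#'
#' @param thesaurus Thesaurus tibble.
#' @param disease_id Identifier for the disease.
#' @param search_strings Search strings for network retrieval.
#' @param decisions Optional decision tibble (default: keep everything).
#' @return A tibble with columns disease_id, term.
#' @export
build_lexicon <- function(thesaurus, disease_id, search_strings,
                          decisions = NULL) {
  if (is.null(thesaurus) || !nrow(thesaurus)) {
    warn(sprintf("empty thesaurus: lexicon for '%s' is empty", disease_id))
    return(tibble::tibble(disease_id = character(), term = character()))
  }
  candidates <- retrieve_candidate_networks(thesaurus, search_strings)
  vetted <- apply_decision_file(candidates, decisions)
  chv_forms <- stringr::str_to_lower(thesaurus$chv_term)
  terms <- structural_reduce(vetted, prefer = chv_forms)
  tibble::tibble(disease_id = disease_id, term = terms)
}

#' Build lexica for several diseases
#'
#' @param thesaurus Thesaurus tibble.
#' @param diseases Named list: disease id -> character vector of search
#'   strings.
#' @param decisions Optional named list of decision tibbles keyed by disease
#'   id.
#' @return A tibble with columns disease_id, term (all lexica stacked).
#' @export
build_lexica <- function(thesaurus, diseases, decisions = NULL) {
  purrr::imap(diseases, function(strings, id) {
    build_lexicon(thesaurus, id, strings, decisions[[id]])
  }) |>
    dplyr::bind_rows()
}
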