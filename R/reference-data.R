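# Bundled reference dataset: per-disease raw and validated tweet counts for
# 24 diseases measured on a year-long 2012 US Twitter sample, together with
# two-stratum prevalence (general US population and US Twitter users) from a
# poststratified national consumer survey. Counts for two cardiovascular
# pairs were measured separately but surveyed collapsed; the bundled merge
# map reduces the 24 count rows to the 22 analysis diseases.

#' Bundled disease-mention counts (24 pre-merge rows)
#'
#' @return A tibble (disease_id, rcount, vcount, correction_factor).
#' @export
reference_counts <- function() {
  readr::read_csv(
    system.file("extdata", "disease_counts_2012.csv", package = "diseasetalk"),
    col_types = readr::cols(disease_id = "c", rcount = "d", vcount = "d",
                            correction_factor = "d"))
}

#' Bundled two-stratum prevalence (22 analysis diseases, persons)
#'
#' @return A tibble (disease_id, prev_general, prev_platform).
#' @export
reference_prevalence <- function() {
  read_prevalence(system.file("extdata", "disease_prevalence_2012.csv",
                              package = "diseasetalk"))
}

#' Bundled merge map (24 count rows -> 22 analysis diseases)
#'
#' @return A named list of character vectors.
#' @export
reference_merge_map <- function() {
  yaml::read_yaml(system.file("extdata", "merge_map.yaml",
                              package = "diseasetalk"))
}

#' Bundled analysis records: counts merged with prevalence
#'
#' @return A tibble of 22 rows (disease_id, rcount, vcount,
#'   correction_factor, prev_general, prev_platform).
#' @export
reference_records <- function() {
  merge_counts(reference_counts(), reference_merge_map(),
               reference_prevalence())
}
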