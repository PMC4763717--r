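# Prevalence analysis: merging counts with two-stratum prevalence, tie-aware
# Spearman correlation, prevalence projection and representation ratios.
#
# The demographic correction is realised entirely by the choice of
# prevalence column: correlating counts against prevalence within the
# platform-user stratum instead of the general population.

#' Read a two-stratum prevalence table
#'
#' Schema: disease_id, prev_general, prev_platform, units (persons |
#' millions). Internally everything is carried in persons.
#'
#' @param path CSV path.
#' @return A tibble (disease_id, prev_general, prev_platform) in persons.
#' @export
read_prevalence <- function(path) {
  p <- readr::read_csv(path, col_types = readr::cols(
    disease_id = "c", prev_general = "d", prev_platform = "d",
    .default = "c"))
  need <- c("disease_id", "prev_general", "prev_platform")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    input_error("prevalence table is missing columns: %s",
                paste(miss, collapse = ", "))
  }
  units <- if ("units" %in% names(p)) p$units else "persons"
  bad <- setdiff(unique(units), c("persons", "millions"))
  if (length(bad)) input_error("unknown prevalence units: %s", paste(bad, collapse = ", "))
  scale <- ifelse(units == "millions", 1e6, 1)
  tibble::tibble(disease_id = p$disease_id,
                 prev_general = p$prev_general * scale,
                 prev_platform = p$prev_platform * scale)
}

#' Merge per-lexicon counts to the analysis disease set
#'
#' Prevalence surveys sometimes collapse conditions that were counted
#' separately (congestive heart failure with heart disease; heart attack
#' with stroke). The merge map lists, for each analysis disease, the count
#' rows whose raw and validated counts are summed into it; diseases absent
#' from the map pass through unchanged.
#'
#' @param corrections Lexicon-correction tibble (disease_id, rcount, vcount)
#'   from [lexicon_correction()] (extra columns ignored).
#' @param merge_map Named list: analysis disease id -> character vector of
#'   input disease ids. `NULL` for the identity map.
#' @param prevalence Prevalence tibble in persons (see [read_prevalence()]).
#' @return A tibble (disease_id, rcount, vcount, correction_factor,
#'   prev_general, prev_platform), one row per analysis disease.
#' @export
merge_counts <- function(corrections, merge_map = NULL, prevalence) {
  inputs <- unlist(merge_map, use.names = FALSE)
  if (anyDuplicated(inputs)) {
    input_error("merge map inputs must be disjoint")
  }
  missing_in <- setdiff(inputs, corrections$disease_id)
  if (length(missing_in)) {
    input_error("merge map references unknown count rows: %s",
                paste(missing_in, collapse = ", "))
  }
  passthrough <- setdiff(corrections$disease_id, inputs)
  full_map <- c(as.list(setNames(passthrough, passthrough)), merge_map)

  merged <- purrr::imap(full_map, function(sources, out_id) {
    rows <- corrections[corrections$disease_id %in% sources, ]
    tibble::tibble(disease_id = out_id,
                   rcount = sum(rows$rcount), vcount = sum(rows$vcount))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(correction_factor = dplyr::if_else(
      .data$rcount > 0, 100 * .data$vcount / .data$rcount, NA_real_))

  no_prev <- setdiff(merged$disease_id, prevalence$disease_id)
  if (length(no_prev)) {
    input_error("no prevalence record for: %s", paste(no_prev, collapse = ", "))
  }
  dplyr::inner_join(merged, prevalence, by = "disease_id") |>
    dplyr::arrange(.data$disease_id)
}

# Mid-ranks computed directly (ties get the average of the ranks they span).
.midrank <- function(v) {
  ord <- order(v)
  sv <- v[ord]
  n <- length(v)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sv[j + 1L] == sv[i]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Tie-aware Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; ties receive the average of the ranks
#' they occupy. Returns `NA` with a warning when either rank vector is
#' constant.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) input_error("x and y must have equal length")
  if (length(x) < 3) input_error("need at least 3 observations")
  rx <- .midrank(x)
  ry <- .midrank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0) {
    warn("constant ranks: Spearman correlation undefined")
    return(NA_real_)
  }
  sum(dx * dy) / denom
}

#' Permutation test for Spearman correlation
#'
#' Two-sided p-value from seeded random permutations of one rank vector;
#' uses the add-one estimator (1 + #extreme) / (n_perm + 1).
#'
#' @param x,y Numeric vectors.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A list with `rho` and `p_value`.
#' @export
spearman_perm_test <- function(x, y, n_perm = 10000, seed = 1L) {
  rho <- spearman_rho(x, y)
  rx <- .midrank(x)
  ry <- .midrank(y)
  dx <- rx - mean(rx)
  sdx <- sqrt(sum(dx^2))
  extreme <- withr::with_seed(substream_seed(seed, "perm"), {
    sum(vapply(seq_len(n_perm), function(i) {
      py <- ry[sample.int(length(ry))]
      dy <- py - mean(py)
      r <- sum(dx * dy) / (sdx * sqrt(sum(dy^2)))
      abs(r) >= abs(rho) - 1e-12
    }, logical(1)))
  })
  list(rho = rho, p_value = (1 + extreme) / (n_perm + 1))
}

#' The 2x2 correlation table: counts x prevalence strata
#'
#' Spearman correlations of raw and validated counts against general-
#' population and platform-user prevalence. Moving along the validated row
#' applies the ambiguity correction; moving to the platform column applies
#' the demographic correction.
#'
#' @param records Merged count/prevalence tibble from [merge_counts()].
#' @return A tibble (count_type, prev_general, prev_platform) with two rows,
#'   `raw` and `validated`.
#' @export
correlation_table <- function(records) {
  if (nrow(records) < 3) input_error("need at least 3 diseases")
  tibble::tibble(
    count_type = c("raw", "validated"),
    prev_general = c(spearman_rho(records$rcount, records$prev_general),
                     spearman_rho(records$vcount, records$prev_general)),
    prev_platform = c(spearman_rho(records$rcount, records$prev_platform),
                      spearman_rho(records$vcount, records$prev_platform))
  )
}

#' Projected prevalence from validated counts
#'
#' For each disease d: projected(d) = (vcount_d / sum of all vcounts) * sum
#' of all actual prevalence — the prevalence the validated mention share
#' would (inaccurately) imply. The projected total equals the actual total
#' by construction; the conservation check is asserted to 1e-9 relative.
#'
#' @param records Merged count/prevalence tibble from [merge_counts()].
#' @param stratum Which prevalence column to project onto (default
#'   "prev_general").
#' @return A tibble (disease_id, vcount, projected_prevalence,
#'   actual_prevalence, representation_ratio).
#' @export
projected_prevalence <- function(records, stratum = "prev_general") {
  total_v <- sum(records$vcount)
  if (total_v <= 0) input_error("all validated counts are zero")
  actual <- records[[stratum]]
  total_p <- sum(actual)
  projected <- records$vcount / total_v * total_p
  stopifnot(abs(sum(projected) - total_p) <= 1e-9 * total_p)
  tibble::tibble(
    disease_id = records$disease_id,
    vcount = records$vcount,
    projected_prevalence = projected,
    actual_prevalence = actual,
    representation_ratio = dplyr::if_else(actual > 0, projected / actual,
                                          NA_real_)
  )
}

#' Over/under-representation report
#'
#' Sorts the projection table by projected prevalence (descending) and flags
#' diseases whose discussion share exceeds their prevalence share
#' (ratio > 1) as over-represented.
#'
#' @param projection Tibble from [projected_prevalence()].
#' @return The sorted tibble with an `over_represented` logical column.
#' @export
representation_report <- function(projection) {
  projection |>
    dplyr::arrange(dplyr::desc(.data$projected_prevalence)) |>
    dplyr::mutate(over_represented = !is.na(.data$representation_ratio) &
                    .data$representation_ratio > 1)
}

#' Paired-bar chart of projected versus actual prevalence
#'
#' Cosmetic companion to [representation_report()]; the report tibble is the
#' canonical output.
#'
#' @param projection Tibble from [projected_prevalence()].
#' @return A ggplot object.
#' @export
plot_representation <- function(projection) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    input_error("ggplot2 is required for plotting")
  }
  dat <- representation_report(projection) |>
    tidyr::pivot_longer(c("projected_prevalence", "actual_prevalence"),
                        names_to = "series", values_to = "prevalence")
  dat$disease_id <- factor(dat$disease_id, levels = rev(unique(dat$disease_id)))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$prevalence / 1e6, y = .data$disease_id, fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Prevalence (millions)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
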