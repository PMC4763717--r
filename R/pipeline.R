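# End-to-end orchestration: YAML configuration, staged runs with a
# provenance manifest, and the one-command reproduction of the bundled
# reference analysis.

#' Read a pipeline configuration
#'
#' YAML with a `mode` (full | from-counts), a `paths` block and a
#' `parameters` block. In from-counts mode only counts and prevalence paths
#' are required; full mode additionally needs thesaurus, diseases (search
#' strings), tweets, dictionary, gazetteer and judgments.
#'
#' @param path YAML path.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$mode <- cfg$mode %||% "from-counts"
  if (!cfg$mode %in% c("full", "from-counts")) {
    input_error("unknown pipeline mode: %s", cfg$mode)
  }
  cfg$parameters <- cfg$parameters %||% list()
  cfg$parameters$k <- cfg$parameters$k %||% 30
  cfg$parameters$seed <- cfg$parameters$seed %||% 1L
  need <- if (cfg$mode == "from-counts") {
    c("counts", "prevalence")
  } else {
    c("thesaurus", "tweets", "dictionary", "gazetteer", "judgments")
  }
  for (p in need) {
    if (is.null(cfg$paths[[p]])) {
      input_error("config mode '%s' requires paths$%s", cfg$mode, p)
    }
    if (!file.exists(cfg$paths[[p]])) {
      input_error("configured path does not exist: %s", cfg$paths[[p]])
    }
  }
  cfg
}

# Stage wrapper: abort with the stage name on any error.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "diseasetalk_stage_error")
  })
}

#' Run the full measurement pipeline
#'
#' Executes the configured stages and writes every stage output plus a
#' provenance manifest (input hashes, seeds, package version, stage row
#' counts) into `out_dir`. Outputs are deterministic given the same config
#' and inputs.
#'
#' @param config Config list from [read_pipeline_config()] (or an equivalent
#'   list).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("diseasetalk")),
    mode = config$mode,
    parameters = config$parameters,
    inputs = lapply(config$paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = list()
  )
  note <- function(stage, n) manifest$stages[[stage]] <<- list(rows = n)

  if (config$mode == "full") {
    lexica <- .stage("lexicon", {
      thesaurus <- read_thesaurus(config$paths$thesaurus)
      decisions <- NULL
      if (!is.null(config$paths$decisions)) {
        decisions <- lapply(config$paths$decisions, read_decision_file)
      }
      build_lexica(thesaurus, config$diseases, decisions)
    })
    readr::write_csv(lexica, file.path(out_dir, "lexica.csv"))
    note("lexicon", nrow(lexica))

    filtered <- .stage("filter", {
      filter_corpus(config$paths$tweets,
                    read_dictionary(config$paths$dictionary),
                    read_gazetteer(config$paths$gazetteer))
    })
    note("filter", nrow(filtered$tweets))

    index <- .stage("match", match_terms(filtered$tweets, lexica))
    readr::write_csv(index, file.path(out_dir, "match_index.csv"))
    counts <- raw_counts(index, lexica)
    readr::write_csv(counts, file.path(out_dir, "raw_counts.csv"))
    note("match", nrow(index))

    samples <- .stage("sample", {
      draw_samples(index, k = config$parameters$k,
                   seed = config$parameters$seed)
    })
    readr::write_csv(samples, file.path(out_dir, "samples.csv"))
    note("sample", nrow(samples))

    corrections <- .stage("correction", {
      judgments <- read_judgments(config$paths$judgments)
      term_corrections(judgments, counts)
    })
    readr::write_csv(corrections, file.path(out_dir, "term_corrections.csv"))
    lexcor <- lexicon_correction(corrections)
    readr::write_csv(lexcor, file.path(out_dir, "lexicon_corrections.csv"))
    note("correction", nrow(lexcor))
    counts_for_analysis <- lexcor[, c("disease_id", "rcount", "vcount")]
  } else {
    counts_for_analysis <- .stage("load-counts", {
      readr::read_csv(config$paths$counts,
                      col_types = readr::cols(disease_id = "c", rcount = "d",
                                              vcount = "d", .default = "c"))
    })
    note("load-counts", nrow(counts_for_analysis))
  }

  if (!is.null(config$paths$prevalence)) {
    records <- .stage("merge", {
      merge_map <- NULL
      if (!is.null(config$paths$merge_map)) {
        merge_map <- yaml::read_yaml(config$paths$merge_map)
      }
      merge_counts(counts_for_analysis, merge_map,
                   read_prevalence(config$paths$prevalence))
    })
    readr::write_csv(records, file.path(out_dir, "analysis_records.csv"))
    note("merge", nrow(records))

    cors <- .stage("correlate", correlation_table(records))
    readr::write_tsv(cors, file.path(out_dir, "correlation_table.tsv"))
    proj <- .stage("project", projected_prevalence(records))
    readr::write_tsv(representation_report(proj),
                     file.path(out_dir, "projection.tsv"))
    note("analysis", nrow(proj))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Reproduce the bundled reference analysis
#'
#' Runs the from-counts analysis on the bundled 2012 dataset: merges the 24
#' count rows to 22 analysis diseases, computes the 2x2 Spearman correlation
#' table, the projected prevalence of every disease and its representation
#' ratio, and re-derives the worked-example quantities (the diabetes
#' validated count, the stroke and arthritis weighted percentages, the
#' merged cardiovascular factors). Requires no network access.
#'
#' @return A list with `records`, `correlations`, `projection` and `checks`
#'   (a tibble of recomputed worked-example values).
#' @export
reproduce_study <- function() {
  records <- reference_records()
  cors <- correlation_table(records)
  proj <- representation_report(projected_prevalence(records))
  counts <- reference_counts()

  val <- function(id, col) counts[[col]][counts$disease_id == id]
  rec <- function(id, col) records[[col]][records$disease_id == id]
  checks <- tibble::tibble(
    quantity = c("diabetes_vcount_rounded", "stroke_weighted_percent",
                 "arthritis_weighted_percent", "heart_attack_stroke_factor",
                 "projected_total_persons"),
    value = c(
      round(val("diabetes", "rcount") * val("diabetes", "correction_factor") / 100),
      round(100 * val("stroke", "vcount") / val("stroke", "rcount"), 2),
      round(100 * val("arthritis", "vcount") / val("arthritis", "rcount"), 2),
      round(rec("heart_attack_stroke", "correction_factor"), 2),
      sum(proj$projected_prevalence)
    )
  )
  list(records = records, correlations = cors, projection = proj,
       checks = checks)
}
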