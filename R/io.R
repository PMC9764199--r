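#' Read a per-nucleus intensity table
#'
#' Reads a CSV of per-object measurements (as produced by segmentation
#' software), optionally renaming columns through a mapping, validates the
#' required intensity columns, and drops rows with missing or negative
#' intensities (count reported as a message). Ground-truth columns
#' (prefix `truth_`) are loaded but recorded in the `"truth_columns"`
#' attribute; analysis operations never read them.
#'
#' @param path CSV path with a header row.
#' @param col_map Optional named character vector mapping package column
#'   names to file column names, e.g.
#'   `c(dna_total = "Intensity_IntegratedIntensity_Hoechst")`.
#' @param required Columns that must be present after mapping.
#' @return A validated tibble.
#' @export
read_nucleus_table <- function(path, col_map = NULL,
                               required = c("sample", "dna_total",
                                            "edu_total")) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "cc_schema_error")
  }
  # base read.csv: strtod parsing is correctly rounded, so tables written
  # with 17 significant digits round-trip exactly
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(df))
    if (length(missing_src) > 0) {
      abort(paste0("Mapped column(s) absent from file: ",
                   paste(missing_src, collapse = ", ")),
            class = "cc_schema_error")
    }
    df <- dplyr::rename(df, !!!setNames(col_map, names(col_map)))
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cc_schema_error")
  }
  intensity_cols <- setdiff(required, "sample")
  bad <- rep(FALSE, nrow(df))
  for (col in intensity_cols) {
    bad <- bad | !is.finite(df[[col]]) | df[[col]] < 0
  }
  if (any(bad)) {
    inform(sprintf("read_nucleus_table: dropped %d row(s) with missing or negative intensities.",
                   sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "truth_columns") <- grep("^truth_", names(df), value = TRUE)
  attr(df, "n_dropped") <- sum(bad)
  df
}

#' Write a per-nucleus table as CSV
#'
#' Doubles are written with 17 significant digits so a write-then-read
#' round trip reproduces them bit for bit.
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over Biostrings for multi-record, line-wrapped FASTA.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: tibble with `seq_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(seq_id = names(ss),
                 sequence = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @param sequences Tibble with `seq_id`, `sequence` (as from
#'   [generate_promoter_set()]) or a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$seq_id)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Run the simulate-gate-marker-replication pipeline
#'
#' Executes the imaging-cytometry stages in order — simulate (or read) the
#' per-nucleus tables, gate, summarise markers, summarise replication
#' rate — and writes every result plus a run manifest (resolved config,
#' seed, package version) to `out_dir`. Any stage error aborts with the
#' stage name; outputs written before the failure are preserved.
#'
#' @param config A nested list (or YAML path read with
#'   [yaml::read_yaml()]): `samples` (named list of
#'   [cell_cycle_config()] argument lists), optional `input_csv` instead,
#'   `markers` (character vector of marker columns), `gating`
#'   (arguments to [gate_cells()]), `seed`, `out_dir`.
#' @return Named list of result tibbles, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "cc_pipeline_error")
    })
  }

  cells <- if (!is.null(config$input_csv)) {
    stage("read", read_nucleus_table(config$input_csv,
                                     col_map = config$col_map))
  } else {
    stage("simulate", {
      specs <- config$samples %||% list(sample1 = list())
      dplyr::bind_rows(purrr::imap(specs, function(args, name) {
        args$sample <- name
        args$seed <- args$seed %||% seed
        if (!is.null(args$phase_fractions)) {
          args$phase_fractions <- unlist(args$phase_fractions)
        }
        do.call(cell_cycle_config, args) |> simulate_population()
      }))
    })
  }
  write_nucleus_table(cells, file.path(out_dir, "nuclei.csv"))

  labeled <- stage("gate", {
    do.call(gate_cells, c(list(data = cells), config$gating))
  })
  models <- attr(labeled, "gating_models")
  fractions <- phase_fractions(labeled)
  readr::write_tsv(fractions, file.path(out_dir, "phase_fractions.tsv"),
                   progress = FALSE)
  report <- purrr::map_dfr(models, glance_gating_row)
  readr::write_tsv(report, file.path(out_dir, "gating_report.tsv"),
                   progress = FALSE)

  markers <- config$markers %||% intersect(c("mcm2", "p21"), names(cells))
  marker_summaries <- stage("marker", {
    purrr::map_dfr(markers, function(m) {
      ref <- labeled[[m]][labeled$phase == "G2M"]
      thr <- fit_positivity_threshold(labeled[[m]],
                                      method = "reference_quantile",
                                      reference = ref)
      percent_positive_by_phase(labeled, m, thr)
    })
  })
  readr::write_tsv(marker_summaries,
                   file.path(out_dir, "marker_summary.tsv"),
                   progress = FALSE)

  replication <- stage("replication", s_phase_edu_summary(labeled))
  readr::write_tsv(replication, file.path(out_dir, "replication.tsv"),
                   progress = FALSE)

  manifest <- list(
    package = "cyclegate",
    version = as.character(utils::packageVersion("cyclegate")),
    seed = seed,
    config = config,
    outputs = c("nuclei.csv", "phase_fractions.tsv", "gating_report.tsv",
                "marker_summary.tsv", "replication.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(list(cells = cells, labeled = labeled, fractions = fractions,
                 gating_report = report, markers = marker_summaries,
                 replication = replication))
}

glance_gating_row <- function(model) {
  tibble::tibble(
    sample = model$sample %||% NA_character_,
    g1_peak = model$dna_scale$g1_peak,
    g2_peak = model$dna_scale$g2_peak,
    imputed_4n = model$dna_scale$imputed_4n,
    edu_threshold = model$edu_threshold,
    edu_method = model$edu_method,
    n = model$dna_scale$n)
}
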