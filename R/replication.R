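#' S-phase EdU incorporation summary
#'
#' Per-sample DNA-synthesis-rate statistics over S-phase cells only
#' (Early S, S1 and Late S): mean and median total EdU and the 95th
#' percentile of total EdU — the "maximal replication rate" statistic.
#' Percentiles use linear interpolation between order statistics
#' (quantile type 7), a fixed convention recorded here. Statistics are not
#' background-subtracted by default (the gate already excludes
#' EdU-negative cells); `subtract_background = TRUE` subtracts each
#' sample's G1 median EdU first.
#'
#' @param labeled Labeled table from [gate_cells()].
#' @param edu EdU intensity column name.
#' @param min_s_cells Flag floor for the S-phase cell count (default 100).
#' @param subtract_background Subtract the per-sample G1 median EdU.
#' @param pulse_minutes EdU pulse length recorded alongside the summary
#'   (default 30; intensities scale with pulse length, so comparisons
#'   assume a common pulse).
#' @return Tibble: `sample`, `n_s_cells`, `total_edu_mean`,
#'   `total_edu_median`, `edu_p95`, `pulse_minutes`, `flag`.
#' @export
s_phase_edu_summary <- function(labeled, edu = "edu_total",
                                min_s_cells = 100,
                                subtract_background = FALSE,
                                pulse_minutes = 30) {
  if (!"phase" %in% names(labeled)) {
    abort("`labeled` needs a `phase` column.", class = "cc_schema_error")
  }
  if (!edu %in% names(labeled)) {
    abort(paste0("Missing EdU column: ", edu), class = "cc_schema_error")
  }
  s <- labeled[labeled$phase %in% c("EarlyS", "S1", "LateS"), , drop = FALSE]
  if (nrow(s) == 0) {
    abort("No S-phase cells in any sample.", class = "cc_no_s_error")
  }
  bg <- labeled |>
    dplyr::filter(.data$phase == "G1") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(g1_median = median(.data[[edu]]), .groups = "drop")
  s |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_s_cells = dplyr::n(),
      .edu = list(.data[[edu]]),
      .groups = "drop") |>
    dplyr::left_join(bg, by = "sample") |>
    dplyr::mutate(
      .edu = purrr::pmap(list(.data$.edu, .data$g1_median), function(v, m) {
        if (subtract_background && is.finite(m)) v - m else v
      }),
      total_edu_mean = purrr::map_dbl(.data$.edu, mean),
      total_edu_median = purrr::map_dbl(.data$.edu, median),
      edu_p95 = purrr::map_dbl(.data$.edu,
                               ~ unname(stats::quantile(.x, 0.95, type = 7))),
      pulse_minutes = pulse_minutes,
      flag = dplyr::if_else(.data$n_s_cells < min_s_cells, "low_n",
                            NA_character_)) |>
    dplyr::select("sample", "n_s_cells", "total_edu_mean",
                  "total_edu_median", "edu_p95", "pulse_minutes", "flag")
}
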