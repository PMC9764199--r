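#' Fit a marker positivity threshold
#'
#' Three auditable conventions for cutting marker-negative from
#' marker-positive nuclei, all operating on log intensity:
#'
#' * `"reference_quantile"` (recommended for chromatin-bound MCM2): the
#'   `quantile` quantile (default 0.99) of a stated negative-reference
#'   population — e.g. G2/M cells, which have unloaded their MCM.
#' * `"otsu"`: the cut maximising between-class variance of log values.
#' * `"mixture"`: a two-component Gaussian mixture on log values;
#'   threshold at the equal-posterior point between the component means.
#'
#' @param values Numeric marker intensities (> 0).
#' @param method One of `"otsu"`, `"mixture"`, `"reference_quantile"`.
#' @param reference Negative-reference intensities (required for
#'   `"reference_quantile"`).
#' @param quantile Reference quantile (default 0.99).
#' @param min_values Minimum number of values required (default 200).
#' @return A single threshold on the intensity scale.
#' @export
fit_positivity_threshold <- function(values,
                                     method = c("reference_quantile", "otsu",
                                                "mixture"),
                                     reference = NULL, quantile = 0.99,
                                     min_values = 200) {
  method <- match.arg(method)
  values <- values[is.finite(values) & values > 0]
  if (length(values) < min_values) {
    abort(sprintf("Need >= %d marker values (got %d).", min_values,
                  length(values)),
          class = "cc_insufficient_data_error")
  }
  if (method == "reference_quantile") {
    if (is.null(reference)) {
      abort("`reference` values are required for method = \"reference_quantile\".",
            class = "cc_schema_error")
    }
    return(unname(stats::quantile(reference, quantile, type = 7)))
  }
  lx <- log(values)
  if (diff(range(lx)) < sqrt(.Machine$double.eps)) {
    abort("Degenerate constant marker input.", class = "cc_fit_error")
  }
  if (method == "otsu") {
    return(exp(otsu_cut(lx)))
  }
  fit <- Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) abort("Mixture fit failed.", class = "cc_fit_error")
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  pro <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sdv <- sdv[o]; pro <- pro[o]
  post_diff <- function(x) {
    pro[1] * stats::dnorm(x, mu[1], sdv[1]) -
      pro[2] * stats::dnorm(x, mu[2], sdv[2])
  }
  cut <- tryCatch(uniroot(post_diff, lower = mu[1], upper = mu[2])$root,
                  error = function(e) mean(mu))
  exp(cut)
}

# Otsu's between-class variance maximisation on a 256-bin histogram.
otsu_cut <- function(lx) {
  h <- graphics::hist(lx, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # centre of the maximising plateau (an empty gap between classes gives a
  # flat maximum; cut in its middle)
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  mids[best[ceiling(length(best) / 2)]]
}

#' Percent marker-positive cells by cell-cycle phase
#'
#' For each sample and phase, the percentage of cells whose marker
#' intensity strictly exceeds the threshold (values equal to the threshold
#' count negative — a fixed convention so counts are reproducible). Phases
#' with fewer than `min_cells` cells are flagged `"low_n"`, and empty
#' phases are reported with `n_cells = 0` and `percent_positive = NA`
#' rather than dropped.
#'
#' @param labeled Labeled table from [gate_cells()].
#' @param marker Marker column name (e.g. `"mcm2"`).
#' @param threshold Positivity threshold (see [fit_positivity_threshold()]).
#' @param min_cells Flag floor per phase (default 50).
#' @return Tibble: `sample`, `marker`, `phase`, `n_cells`,
#'   `percent_positive`, `median_intensity`, `flag`.
#' @export
percent_positive_by_phase <- function(labeled, marker, threshold,
                                      min_cells = 50) {
  if (!marker %in% names(labeled)) {
    abort(paste0("Unknown marker column: ", marker),
          class = "cc_schema_error")
  }
  if (!"phase" %in% names(labeled)) {
    abort("`labeled` needs a `phase` column.", class = "cc_schema_error")
  }
  labeled |>
    dplyr::group_by(.data$sample, .data$phase, .drop = FALSE) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      percent_positive = if (dplyr::n() == 0) NA_real_ else
        100 * mean(.data[[marker]] > threshold),
      median_intensity = if (dplyr::n() == 0) NA_real_ else
        median(.data[[marker]]),
      .groups = "drop") |>
    dplyr::mutate(
      marker = marker,
      flag = dplyr::case_when(.data$n_cells == 0 ~ "empty",
                              .data$n_cells < min_cells ~ "low_n",
                              .default = NA_character_)) |>
    dplyr::relocate("marker", .after = "sample")
}

#' Smoothed per-phase marker density
#'
#' Kernel density estimates of log marker intensity, evaluated on one
#' shared grid across all samples and phases (the pooled 1st-99th log
#' percentile range, 512 points) so treatments overlay directly. Each
#' curve is renormalised to integrate to 1 on the grid (trapezoidal rule).
#'
#' @inheritParams percent_positive_by_phase
#' @param phases Phases to include (default all present with enough cells).
#' @param min_cells Minimum cells per sample-phase curve (default 50).
#' @param n_grid Grid size.
#' @param bandwidth_mult Multiplier on the Silverman bandwidth; a small
#'   absolute floor keeps degenerate inputs representable as a sharp mode.
#' @return Tibble: `sample`, `marker`, `phase`, `log_intensity`,
#'   `intensity`, `density` (per unit log intensity).
#' @export
marker_density_by_phase <- function(labeled, marker,
                                    phases = NULL, min_cells = 50,
                                    n_grid = 512, bandwidth_mult = 1) {
  if (!marker %in% names(labeled)) {
    abort(paste0("Unknown marker column: ", marker),
          class = "cc_schema_error")
  }
  df <- labeled |>
    dplyr::filter(.data[[marker]] > 0) |>
    dplyr::mutate(.lx = log(.data[[marker]]))
  if (!is.null(phases)) df <- df[df$phase %in% phases, , drop = FALSE]
  grid <- seq(stats::quantile(df$.lx, 0.01), stats::quantile(df$.lx, 0.99),
              length.out = n_grid)
  groups <- df |> dplyr::group_by(.data$sample, .data$phase)
  keys <- dplyr::group_keys(groups)
  curves <- dplyr::group_split(groups)
  out <- purrr::map2_dfr(curves, seq_len(nrow(keys)), function(g, i) {
    if (nrow(g) < min_cells) {
      abort(sprintf("Phase %s in sample %s has %d cells (< %d).",
                    keys$phase[i], keys$sample[i], nrow(g), min_cells),
            class = "cc_insufficient_data_error")
    }
    bw <- max(bw.nrd0(g$.lx) * bandwidth_mult, 0.01)
    d <- density(g$.lx, bw = bw, from = min(grid), to = max(grid),
                 n = n_grid)
    y <- d$y / trapz(grid, d$y)
    tibble::tibble(sample = keys$sample[i], marker = marker,
                   phase = keys$phase[i], log_intensity = grid,
                   intensity = exp(grid), density = y)
  })
  out
}

# trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
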