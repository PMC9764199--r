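# Local maxima of a density object; returns tibble(x, y) sorted by height.
density_modes <- function(d) {
  y <- d$y
  i <- which(diff(sign(diff(y))) == -2) + 1
  # plateaus / boundary maxima
  if (length(i) == 0 && length(y) > 1) i <- which.max(y)
  tibble::tibble(x = d$x[i], y = y[i]) |> dplyr::arrange(dplyr::desc(.data$y))
}

log_density <- function(x, bandwidth_mult = 1) {
  bw <- bw.nrd0(x) * bandwidth_mult
  if (!is.finite(bw) || bw <= 0) return(NULL)
  density(x, bw = bw, n = 512)
}

#' Fit the per-sample DNA 2N/4N scale
#'
#' Kernel-density estimation on log DNA intensity (Silverman's rule times a
#' configurable multiplier) locates the 2N mode as the largest-mass mode;
#' the 4N mode is the highest mode whose position lies within 1.7-2.3 times
#' the 2N peak (the plausible ratio band for a DNA stain), and is imputed
#' at exactly twice the 2N peak — flagged `imputed_4n` — when no mode falls
#' in that band.
#'
#' @param data Per-nucleus data frame.
#' @param sample Optional sample label to filter on (column `sample`).
#' @param dna Name of the DNA intensity column.
#' @param min_cells Minimum nuclei required (default 500).
#' @param halfwidth Relative half-width of the 2N and 4N gates (fraction of
#'   the peak position, default 0.15).
#' @param bandwidth_mult Multiplier on the Silverman KDE bandwidth.
#' @return An object of class `cc_dna_scale`: `g1_peak`, `g2_peak`,
#'   `g1_halfwidth`, `g2_halfwidth`, `imputed_4n`, `sample`, `n`.
#' @export
fit_dna_scale <- function(data, sample = NULL, dna = "dna_total",
                          min_cells = 500, halfwidth = 0.15,
                          bandwidth_mult = 1) {
  if (!dna %in% names(data)) {
    abort(paste0("Missing DNA column: ", dna), class = "cc_schema_error")
  }
  if (!is.null(sample)) data <- data[data$sample == sample, , drop = FALSE]
  x <- data[[dna]]
  x <- x[is.finite(x) & x > 0]
  if (length(x) < min_cells) {
    abort(sprintf("Need >= %d nuclei to fit a DNA scale (got %d).",
                  min_cells, length(x)),
          class = "cc_insufficient_data_error")
  }
  lx <- log(x)
  if (diff(range(lx)) < sqrt(.Machine$double.eps)) {
    # degenerate (constant) input: the single value is the 2N peak
    g1 <- x[1]
    return(new_dna_scale(g1, 2 * g1, halfwidth, TRUE, sample, length(x)))
  }
  d <- log_density(lx, bandwidth_mult)
  if (is.null(d)) {
    abort("Could not form a density estimate for the DNA distribution.",
          class = "cc_fit_error")
  }
  modes <- density_modes(d)
  if (nrow(modes) == 0) {
    abort("No density mode found: flat DNA distribution.",
          class = "cc_fit_error")
  }
  g1 <- exp(modes$x[1])
  band <- modes |>
    dplyr::filter(exp(.data$x) / g1 >= 1.7, exp(.data$x) / g1 <= 2.3)
  if (nrow(band) > 0) {
    new_dna_scale(g1, exp(band$x[1]), halfwidth, FALSE, sample, length(x))
  } else {
    new_dna_scale(g1, 2 * g1, halfwidth, TRUE, sample, length(x))
  }
}

new_dna_scale <- function(g1_peak, g2_peak, halfwidth, imputed_4n,
                          sample, n) {
  structure(
    list(g1_peak = g1_peak, g2_peak = g2_peak,
         g1_halfwidth = halfwidth, g2_halfwidth = halfwidth,
         imputed_4n = imputed_4n, sample = sample, n = n),
    class = "cc_dna_scale"
  )
}

#' @export
print.cc_dna_scale <- function(x, ...) {
  cat(sprintf(
    "<cc_dna_scale> 2N peak %.4g, 4N peak %.4g (ratio %.3f%s), halfwidth %.2f, n = %d\n",
    x$g1_peak, x$g2_peak, x$g2_peak / x$g1_peak,
    if (x$imputed_4n) ", imputed" else "", x$g1_halfwidth, x$n))
  invisible(x)
}

#' Fit the per-sample EdU positivity threshold
#'
#' Primary method: on log EdU, locate the minimum-density valley between
#' the two largest KDE modes (background vs S-phase incorporation).
#' Fallback when the distribution is effectively unimodal: the threshold is
#' `exp(mean + 3 sd)` of log EdU among cells inside the 4N DNA gate — a
#' G2-dominated, EdU-negative reference population. The method actually
#' used is recorded.
#'
#' @inheritParams fit_dna_scale
#' @param edu Name of the EdU intensity column.
#' @param dna_scale A fitted [fit_dna_scale()] object (for the fallback's
#'   4N gate).
#' @param min_mode_height Modes below this fraction of the tallest mode's
#'   height are ignored as KDE ripple.
#' @return A list of class `cc_edu_threshold`: `threshold`, `method`
#'   (`"valley"` or `"fallback_4n"`), `sample`.
#' @export
fit_edu_threshold <- function(data, dna_scale, sample = NULL,
                              edu = "edu_total", dna = "dna_total",
                              bandwidth_mult = 1, min_mode_height = 0.1) {
  if (!edu %in% names(data)) {
    abort(paste0("Missing EdU column: ", edu), class = "cc_schema_error")
  }
  stopifnot(inherits(dna_scale, "cc_dna_scale"))
  if (!is.null(sample)) data <- data[data$sample == sample, , drop = FALSE]
  x <- data[[edu]]
  keep <- is.finite(x) & x > 0
  lx <- log(x[keep])
  d <- log_density(lx, bandwidth_mult)
  modes <- if (is.null(d)) tibble::tibble(x = numeric(), y = numeric()) else {
    density_modes(d) |>
      dplyr::filter(.data$y >= min_mode_height * max(.data$y))
  }
  if (nrow(modes) >= 2) {
    lo <- min(modes$x[1:2]); hi <- max(modes$x[1:2])
    between <- d$x > lo & d$x < hi
    valley_y <- min(d$y[between])
    # require a genuine dip: KDE ripple on a unimodal distribution leaves
    # the "valley" nearly as high as the flanking modes
    if (valley_y < 0.5 * min(modes$y[1:2])) {
      valley <- d$x[between][which.min(d$y[between])]
      return(structure(list(threshold = exp(valley), method = "valley",
                            sample = sample),
                       class = "cc_edu_threshold"))
    }
  }
  # fallback: EdU-negative reference = cells in the 4N DNA gate
  dna_x <- data[[dna]][keep]
  in_4n <- abs(dna_x - dna_scale$g2_peak) <=
    dna_scale$g2_halfwidth * dna_scale$g2_peak
  if (!any(in_4n)) {
    abort("Unimodal EdU and no cells in the 4N gate: cannot set a threshold.",
          class = "cc_fit_error")
  }
  ref <- lx[in_4n]
  structure(list(threshold = exp(mean(ref) + 3 * sd(ref)),
                 method = "fallback_4n", sample = sample),
            class = "cc_edu_threshold")
}

#' Fit a complete gating model for one sample
#'
#' Convenience wrapper: fits the DNA scale then the EdU threshold and
#' assembles the phase-boundary parameters. `early_s_dna_max` defaults to
#' the top of the 2N gate (EdU-positive cells whose DNA has not yet left
#' the G1 gate are "Early S"); mid-S ("S1") and late S split at replicated
#' fraction `s1_f_max`, the boundary belonging to S1.
#'
#' @inheritParams fit_edu_threshold
#' @param s1_f_max Replicated-fraction bound separating S1 from late S.
#' @param ... Passed to [fit_dna_scale()] and [fit_edu_threshold()].
#' @return An object of class `cc_gating_model`.
#' @export
fit_gating_model <- function(data, sample = NULL, dna = "dna_total",
                             edu = "edu_total", s1_f_max = 0.5, ...) {
  scale <- fit_dna_scale(data, sample = sample, dna = dna, ...)
  thr <- fit_edu_threshold(data, scale, sample = sample, edu = edu,
                           dna = dna)
  structure(
    list(dna_scale = scale, edu_threshold = thr$threshold,
         edu_method = thr$method,
         early_s_dna_max = scale$g1_peak * (1 + scale$g1_halfwidth),
         s1_f_max = s1_f_max, sample = sample),
    class = "cc_gating_model"
  )
}

#' Construct a gating model from known parameters
#'
#' Builds a `cc_gating_model` directly — useful for applying externally
#' chosen gates or for testing the assignment rules in isolation.
#'
#' @param g1_peak,g2_peak 2N and 4N DNA peak positions (`g2_peak`
#'   defaults to twice `g1_peak`).
#' @param edu_threshold EdU positivity cut (> 0).
#' @param g1_halfwidth,g2_halfwidth Relative gate half-widths in (0, 0.5).
#' @param early_s_dna_max DNA bound below which EdU-positive cells are
#'   Early S; defaults to the top of the 2N gate.
#' @param s1_f_max Replicated-fraction bound separating S1 from late S.
#' @param sample Optional sample label.
#' @return An object of class `cc_gating_model`.
#' @export
gating_model <- function(g1_peak, edu_threshold, g2_peak = 2 * g1_peak,
                         g1_halfwidth = 0.15, g2_halfwidth = 0.15,
                         early_s_dna_max = g1_peak * (1 + g1_halfwidth),
                         s1_f_max = 0.5, sample = NULL) {
  if (g1_peak <= 0 || g2_peak <= g1_peak) {
    abort("Need 0 < g1_peak < g2_peak.", class = "cc_schema_error")
  }
  ratio <- g2_peak / g1_peak
  if (ratio < 1.7 || ratio > 2.3) {
    abort("g2_peak/g1_peak outside the plausible [1.7, 2.3] band.",
          class = "cc_schema_error")
  }
  if (edu_threshold <= 0) {
    abort("`edu_threshold` must be positive.", class = "cc_schema_error")
  }
  if (early_s_dna_max < g1_peak) {
    abort("`early_s_dna_max` must be at least g1_peak.",
          class = "cc_schema_error")
  }
  structure(
    list(dna_scale = structure(
           list(g1_peak = g1_peak, g2_peak = g2_peak,
                g1_halfwidth = g1_halfwidth, g2_halfwidth = g2_halfwidth,
                imputed_4n = FALSE, sample = sample, n = NA_integer_),
           class = "cc_dna_scale"),
         edu_threshold = edu_threshold, edu_method = "manual",
         early_s_dna_max = early_s_dna_max, s1_f_max = s1_f_max,
         sample = sample),
    class = "cc_gating_model"
  )
}

#' @export
print.cc_gating_model <- function(x, ...) {
  cat(sprintf(
    "<cc_gating_model>%s 2N %.4g / 4N %.4g%s; EdU threshold %.4g (%s)\n",
    if (is.null(x$sample)) "" else paste0(" [", x$sample, "]"),
    x$dna_scale$g1_peak, x$dna_scale$g2_peak,
    if (x$dna_scale$imputed_4n) " (imputed)" else "",
    x$edu_threshold, x$edu_method))
  invisible(x)
}

phase_levels <- function() {
  c("G1", "EarlyS", "S1", "LateS", "G2M", "Unclassified")
}

#' Assign each nucleus a cell-cycle phase
#'
#' EdU-negative cells (at or below the threshold) are G1 if their DNA lies
#' in the 2N gate, G2M if in the 4N gate, and Unclassified otherwise.
#' EdU-positive cells are Early S while their DNA remains at or below
#' `early_s_dna_max`; beyond that, the replicated fraction
#' `f = clamp(DNA / g1_peak - 1, 0, 1)` splits S1 (`f <= s1_f_max`,
#' boundary inclusive) from late S. Re-running on an already labeled table
#' replaces the `phase` column.
#'
#' @param data Per-nucleus data frame (one sample).
#' @param model A [fit_gating_model()] object.
#' @param dna,edu Intensity column names.
#' @return The input as a tibble with a `phase` factor column.
#' @export
assign_phases <- function(data, model, dna = "dna_total", edu = "edu_total") {
  if (!all(c(dna, edu) %in% names(data))) {
    abort("Missing DNA or EdU column.", class = "cc_schema_error")
  }
  stopifnot(inherits(model, "cc_gating_model"))
  sc <- model$dna_scale
  dna_x <- data[[dna]]
  edu_x <- data[[edu]]
  in_g1 <- abs(dna_x - sc$g1_peak) <= sc$g1_halfwidth * sc$g1_peak
  in_g2 <- abs(dna_x - sc$g2_peak) <= sc$g2_halfwidth * sc$g2_peak
  pos <- edu_x > model$edu_threshold
  f <- clamp(dna_x / sc$g1_peak - 1, 0, 1)

  phase <- dplyr::case_when(
    !pos & in_g1 ~ "G1",
    !pos & in_g2 ~ "G2M",
    !pos ~ "Unclassified",
    dna_x <= model$early_s_dna_max ~ "EarlyS",
    f <= model$s1_f_max ~ "S1",
    .default = "LateS"
  )
  out <- tibble::as_tibble(data)
  out$phase <- factor(phase, levels = phase_levels())
  out
}

#' Fit and apply gating per sample
#'
#' Splits the table by `sample`, fits a [fit_gating_model()] for each, and
#' assigns phases. Fitted models are attached as the `"gating_models"`
#' attribute (a named list) for reporting via [tidy()]/[glance()].
#'
#' @inheritParams assign_phases
#' @param data Per-nucleus data frame with a `sample` column.
#' @param borrow_scale Optional sample label whose fitted model is applied
#'   to every sample (for release time courses whose own DNA histograms are
#'   distorted by arrest).
#' @param ... Passed to [fit_gating_model()].
#' @return Labeled tibble with attribute `gating_models`.
#' @export
gate_cells <- function(data, dna = "dna_total", edu = "edu_total",
                       borrow_scale = NULL, ...) {
  if (!"sample" %in% names(data)) {
    abort("`data` needs a `sample` column.", class = "cc_schema_error")
  }
  samples <- unique(data$sample)
  models <- list()
  if (!is.null(borrow_scale)) {
    if (!borrow_scale %in% samples) {
      abort("`borrow_scale` sample not present.", class = "cc_schema_error")
    }
    shared <- fit_gating_model(data, sample = borrow_scale, dna = dna,
                               edu = edu, ...)
    models <- setNames(rep(list(shared), length(samples)), samples)
  } else {
    models <- setNames(
      lapply(samples, function(s) {
        fit_gating_model(data, sample = s, dna = dna, edu = edu, ...)
      }),
      samples)
  }
  labeled <- dplyr::bind_rows(lapply(samples, function(s) {
    assign_phases(data[data$sample == s, , drop = FALSE], models[[s]],
                  dna = dna, edu = edu)
  }))
  attr(labeled, "gating_models") <- models
  labeled
}

#' Per-sample cell-cycle phase fractions
#'
#' Counts nuclei per phase and reports, for each sample, the fraction of
#' classified cells in each phase (`fraction`, `NA` for Unclassified) and
#' every phase's share of all cells (`share_total`, which sums to 1). The
#' aggregate S fraction (Early S + S1 + Late S) is available from
#' [s_phase_fraction()].
#'
#' @param labeled Output of [gate_cells()] or [assign_phases()].
#' @return Tibble: `sample`, `phase`, `n_cells`, `fraction`, `share_total`.
#' @export
phase_fractions <- function(labeled) {
  if (!"phase" %in% names(labeled)) {
    abort("`labeled` needs a `phase` column (run gate_cells()).",
          class = "cc_schema_error")
  }
  if (nrow(labeled) == 0) {
    abort("Empty sample: no cells to summarise.", class = "cc_schema_error")
  }
  labeled |>
    dplyr::count(.data$sample, .data$phase, name = "n_cells",
                 .drop = FALSE) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(
      n_classified = sum(.data$n_cells[.data$phase != "Unclassified"]),
      fraction = dplyr::if_else(
        .data$phase == "Unclassified", NA_real_,
        .data$n_cells / .data$n_classified),
      share_total = .data$n_cells / sum(.data$n_cells)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_classified")
}

#' Aggregate S-phase fraction per sample
#'
#' @param labeled Output of [gate_cells()].
#' @return Tibble: `sample`, `n_cells`, `s_fraction` (Early S + S1 +
#'   Late S over classified cells).
#' @export
s_phase_fraction <- function(labeled) {
  phase_fractions(labeled) |>
    dplyr::filter(.data$phase != "Unclassified") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_cells = sum(.data$n_cells),
      s_fraction = sum(.data$fraction[.data$phase %in%
                                        c("EarlyS", "S1", "LateS")]),
      .groups = "drop")
}
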