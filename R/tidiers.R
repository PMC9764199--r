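#' Tidy a fitted gating model
#'
#' One row per fitted parameter, broom style.
#'
#' @param x A [fit_gating_model()] object.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`.
#' @export
tidy.cc_gating_model <- function(x, ...) {
  tibble::tibble(
    term = c("g1_peak", "g2_peak", "g1_halfwidth", "g2_halfwidth",
             "edu_threshold", "early_s_dna_max", "s1_f_max"),
    estimate = c(x$dna_scale$g1_peak, x$dna_scale$g2_peak,
                 x$dna_scale$g1_halfwidth, x$dna_scale$g2_halfwidth,
                 x$edu_threshold, x$early_s_dna_max, x$s1_f_max))
}

#' Glance at a fitted gating model
#'
#' @inheritParams tidy.cc_gating_model
#' @return One-row tibble: sample, peaks, threshold, method flags, n.
#' @export
glance.cc_gating_model <- function(x, ...) {
  glance_gating_row(x)
}

#' Tidy a screen result
#'
#' @param x A [moderated_t_test()] result.
#' @param ... Unused.
#' @return Plain tibble of per-compound statistics with volcano columns
#'   (`delta`, `neg_log10_p`, `q_value`).
#' @export
tidy.cc_screen_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$neg_log10_p <- -log10(out$p_value)
  out
}

#' Glance at a screen result
#'
#' @inheritParams tidy.cc_screen_result
#' @return One-row tibble with the empirical-Bayes hyper-parameters
#'   (`d0` prior df, `s0_sq` prior variance), the contrasted arms and
#'   compound count.
#' @export
glance.cc_screen_result <- function(x, ...) {
  tibble::tibble(
    n_compounds = nrow(x),
    d0 = attr(x, "d0"),
    s0_sq = attr(x, "s0_sq"),
    arm1 = attr(x, "arms")[1],
    arm2 = attr(x, "arms")[2],
    prior_fallback = attr(x, "prior_fallback"))
}
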