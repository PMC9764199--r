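#' Normalize a viability screen plate
#'
#' Blank-corrects each well against the mean blank of its plate and arm,
#' expresses the corrected signal relative to the mean corrected vehicle
#' (DMSO) signal of the same arm, and log2-transforms. Wells whose
#' corrected signal is non-positive are flagged `"nonpositive"` and get
#' `NA` relative viability; the flagged count is reported as a message and
#' stored in the `"n_flagged"` attribute. Adding a constant to every
#' signal of a plate-arm (blanks included) leaves the result unchanged.
#'
#' @param plate Tibble with columns `plate`, `well`, `role`
#'   (`blank`/`vehicle`/`compound`), `arm`, `compound`, `replicate`,
#'   `signal`.
#' @return The input tibble plus `corrected`, `rel_viability`,
#'   `log2_rel_viability`, `flag`.
#' @export
normalize_screen <- function(plate) {
  need <- c("plate", "role", "arm", "signal")
  if (!all(need %in% names(plate))) {
    abort(paste0("Missing plate columns: ",
                 paste(setdiff(need, names(plate)), collapse = ", ")),
          class = "cc_schema_error")
  }
  if (any(plate$signal < 0, na.rm = TRUE)) {
    abort("Signals must be non-negative.", class = "cc_schema_error")
  }
  arms <- unique(plate$arm)
  role_count <- plate |>
    dplyr::count(.data$arm, .data$role) |>
    tidyr::pivot_wider(names_from = "role", values_from = "n",
                       values_fill = 0L)
  if (!"vehicle" %in% names(role_count) || any(role_count$vehicle == 0)) {
    abort("Every arm needs vehicle wells (normalization impossible).",
          class = "cc_normalization_error")
  }
  if (!"blank" %in% names(role_count) || any(role_count$blank == 0)) {
    abort("Every arm needs blank wells.", class = "cc_normalization_error")
  }

  out <- plate |>
    dplyr::group_by(.data$plate, .data$arm) |>
    dplyr::mutate(corrected = .data$signal -
                    mean(.data$signal[.data$role == "blank"])) |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(
      .veh = mean(.data$corrected[.data$role == "vehicle"]),
      rel_viability = .data$corrected / .data$.veh) |>
    dplyr::ungroup()
  if (any(out$.veh <= 0)) {
    abort("Vehicle mean is non-positive after blank correction.",
          class = "cc_normalization_error")
  }
  measured <- out$role != "blank"
  ok <- measured & out$corrected > 0
  lv <- rep(NA_real_, nrow(out))
  lv[ok] <- log2(out$rel_viability[ok])
  out <- out |>
    dplyr::mutate(
      rel_viability = dplyr::if_else(measured, .data$rel_viability,
                                     NA_real_),
      flag = dplyr::if_else(measured & !ok, "nonpositive", NA_character_),
      log2_rel_viability = lv) |>
    dplyr::select(-".veh")
  n_flagged <- sum(!is.na(out$flag))
  if (n_flagged > 0) {
    inform(sprintf("normalize_screen: %d well(s) flagged non-positive and excluded.",
                   n_flagged))
  }
  attr(out, "n_flagged") <- n_flagged
  out
}

# solve trigamma(y) = x for y > 0 (x > 0); trigamma is strictly decreasing
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NA_real_)
    uniroot(function(y) trigamma(y) - xi,
            lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  }, numeric(1))
}

# Method-of-moments fit of the scaled-F model for sample variances:
# s2_g ~ s0^2 * F(d_g, d0). Matches the mean and variance of log s2_g via
# digamma/trigamma identities. Returns list(d0, s0_sq, fallback).
fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0 & dg > 0
  z <- log(s2[ok])
  dgo <- dg[ok]
  if (length(z) < 2) return(list(d0 = 4, s0_sq = mean(s2[ok]), fallback = TRUE))
  e <- z - digamma(dgo / 2) + log(dgo / 2)
  evar <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) -
    mean(trigamma(dgo / 2))
  if (!is.finite(evar) || evar <= 0) {
    # all excess variability explained by chi-square sampling noise; the
    # moment equation has no positive root
    return(list(d0 = 4, s0_sq = exp(mean(e)), fallback = TRUE))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq, fallback = FALSE)
}

#' Empirical-Bayes moderated two-sample t per compound
#'
#' For each compound with replicate log2 relative viabilities in two arms,
#' computes the arm means, their difference `delta` (arm2 minus arm1), the
#' pooled within-compound variance `s_g^2` with `d_g` degrees of freedom,
#' and the moderated statistic built on the posterior variance
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`:
#' `t~ = delta / (s~_g sqrt(1/n1 + 1/n2))`, referred to a t distribution
#' with `d0 + d_g` degrees of freedom (two-sided p). With `d0 = 0` this is
#' exactly the ordinary pooled-variance two-sample t. Hyper-parameters
#' `d0` and `s0^2` are estimated by method-of-moments on `log s_g^2`
#' (digamma/trigamma matching of the scaled-F model); if the moment
#' equation has no positive root the fit falls back to `d0 = 4` with a
#' message. Benjamini-Hochberg q-values are appended.
#'
#' Compounds present in only one arm, or with fewer than 2 usable
#' replicates in either arm, are excluded with a message. Flagged
#' (`NA`) wells are dropped before averaging.
#'
#' @param normalized Output of [normalize_screen()] (or any tibble with
#'   `compound`, `arm`, and a log2 value column), compound rows only.
#' @param arms Length-2 character vector selecting and ordering the arms;
#'   default the first two in the data.
#' @param value Name of the log2 value column.
#' @param d0,s0_sq `"estimate"` (default) or fixed numeric values.
#' @return A tibble of class `cc_screen_result`: `compound`,
#'   `mean_arm1`, `mean_arm2`, `delta`, `s2_pooled`, `df_residual`,
#'   `s2_posterior`, `t`, `df_total`, `p_value`, `q_value`, with
#'   hyper-parameters in attributes (see [glance()]).
#' @export
moderated_t_test <- function(normalized, arms = NULL,
                             value = "log2_rel_viability",
                             d0 = "estimate", s0_sq = "estimate") {
  need <- c("compound", "arm", value)
  if (!all(need %in% names(normalized))) {
    abort(paste0("Missing columns: ",
                 paste(setdiff(need, names(normalized)), collapse = ", ")),
          class = "cc_schema_error")
  }
  df <- normalized |>
    dplyr::filter(!is.na(.data$compound), !is.na(.data[[value]]))
  if (is.null(arms)) arms <- unique(df$arm)[1:2]
  if (length(arms) != 2) {
    abort("Exactly two arms are required.", class = "cc_schema_error")
  }
  df <- df[df$arm %in% arms, , drop = FALSE]

  per <- df |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n1 = sum(.data$arm == arms[1]),
      n2 = sum(.data$arm == arms[2]),
      mean_arm1 = mean(.data[[value]][.data$arm == arms[1]]),
      mean_arm2 = mean(.data[[value]][.data$arm == arms[2]]),
      ss = {
        x1 <- .data[[value]][.data$arm == arms[1]]
        x2 <- .data[[value]][.data$arm == arms[2]]
        sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
      },
      .groups = "drop")
  dropped <- per |> dplyr::filter(.data$n1 < 2 | .data$n2 < 2)
  if (nrow(dropped) > 0) {
    inform(sprintf("moderated_t_test: %d compound(s) excluded (fewer than 2 replicates in an arm).",
                   nrow(dropped)))
  }
  per <- per |> dplyr::filter(.data$n1 >= 2, .data$n2 >= 2)
  if (nrow(per) == 0) {
    abort("No compound has >= 2 replicates in both arms.",
          class = "cc_schema_error")
  }
  per <- per |>
    dplyr::mutate(
      df_residual = .data$n1 + .data$n2 - 2,
      s2_pooled = .data$ss / .data$df_residual,
      delta = .data$mean_arm2 - .data$mean_arm1)

  estimate <- identical(d0, "estimate") || identical(s0_sq, "estimate")
  fallback <- FALSE
  if (estimate) {
    if (all(per$s2_pooled == 0)) {
      abort("Zero within-arm variance for every compound: cannot estimate the variance prior (fix `d0`).",
            class = "cc_fit_error")
    }
    if (nrow(per) < 20) {
      warn("Fewer than 20 compounds: variance-prior estimates are unstable.")
    }
    prior <- fit_variance_prior(per$s2_pooled, per$df_residual)
    if (identical(d0, "estimate")) d0 <- prior$d0
    if (identical(s0_sq, "estimate")) s0_sq <- prior$s0_sq
    fallback <- prior$fallback
    if (fallback) inform("moderated_t_test: variance-prior moment equation had no positive root; using d0 = 4.")
  }
  d0 <- as.numeric(d0)
  if (d0 < 0) abort("`d0` must be >= 0.", class = "cc_schema_error")
  s0_sq <- as.numeric(s0_sq)

  out <- per |>
    dplyr::mutate(
      s2_posterior = if (is.infinite(d0)) s0_sq else
        (d0 * s0_sq + .data$df_residual * .data$s2_pooled) /
        (d0 + .data$df_residual),
      df_total = d0 + .data$df_residual,
      t = .data$delta /
        sqrt(.data$s2_posterior * (1 / .data$n1 + 1 / .data$n2)),
      p_value = 2 * pt(-abs(.data$t), df = .data$df_total),
      q_value = bh_adjust(.data$p_value)) |>
    dplyr::select("compound", "n1", "n2", "mean_arm1", "mean_arm2",
                  "delta", "s2_pooled", "df_residual", "s2_posterior",
                  "t", "df_total", "p_value", "q_value")
  class(out) <- c("cc_screen_result", class(out))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "arms") <- arms
  attr(out, "prior_fallback") <- fallback
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' delegating to [stats::p.adjust()].
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].", class = "cc_schema_error")
  }
  p.adjust(pvalues, method = "BH")
}
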