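#' Configuration for a simulated asynchronous cell population
#'
#' Bundles every parameter of the single-cell generator: the phase mixture,
#' the DNA-stain scale (2N position), the EdU background/incorporation model,
#' chromatin-bound MCM loading, and G1-restricted p21 positivity. All
#' intensities are unitless integrated per-nucleus fluorescence. Noise is
#' multiplicative lognormal throughout (fluorescence is positive and
#' right-skewed), parameterised by a coefficient of variation.
#'
#' @param n_cells Number of nuclei to simulate.
#' @param phase_fractions Named numeric vector over `G1`, `S`, `G2M`
#'   summing to 1; phases may be omitted (fraction 0).
#' @param dna_2n_mean Mean observed DNA intensity of an unreplicated (2N)
#'   nucleus.
#' @param dna_noise_cv CV of the multiplicative DNA measurement noise,
#'   in (0, 0.5); 0 allowed for noiseless checks.
#' @param edu_background_mean,edu_background_cv Lognormal parameters of the
#'   EdU background (click-chemistry background in non-replicating cells).
#' @param edu_rate_scale Peak EdU incorporation signal of an S-phase cell at
#'   full synthesis rate (added on top of background).
#' @param edu_profile Shape of incorporation rate versus replicated fraction
#'   `f`: `"trapezoid"` (ramps over f in \[0, 0.1\] and \[0.9, 1\], flat
#'   between — gives realistic dim early/late-S cells) or `"flat"`.
#' @param mcm_max_mean Mean chromatin-bound MCM2 intensity at the G1/S
#'   transition (fully licensed).
#' @param mcm_noise_cv CV of MCM2 (and p21) measurement noise.
#' @param mcm_g1_loading_exponent MCM loading through G1 follows
#'   `u^exponent` of G1 progress `u`; 1 = linear loading.
#' @param p21_positive_fraction_g1 Fraction of G1 cells in the p21-positive
#'   state.
#' @param marker_positive_level,marker_negative_level Mean intensities of
#'   the positive and negative marker states (p21; also the MCM floor in
#'   G2/M where the helicase is unloaded).
#' @param seed Integer seed; one global stream drives every draw.
#' @param sample Sample label carried into the output table.
#'
#' @return A validated list of class `cc_config`.
#' @seealso [simulate_population()]
#' @export
cell_cycle_config <- function(n_cells = 6000,
                              phase_fractions = c(G1 = 0.5, S = 0.3, G2M = 0.2),
                              dna_2n_mean = 1000,
                              dna_noise_cv = 0.05,
                              edu_background_mean = 50,
                              edu_background_cv = 0.3,
                              edu_rate_scale = 2000,
                              edu_profile = c("trapezoid", "flat"),
                              mcm_max_mean = 800,
                              mcm_noise_cv = 0.2,
                              mcm_g1_loading_exponent = 1,
                              p21_positive_fraction_g1 = 0.5,
                              marker_positive_level = 500,
                              marker_negative_level = 20,
                              seed = 1L,
                              sample = "sample1") {
  edu_profile <- match.arg(edu_profile)
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
    abort("`n_cells` must be a positive count.", class = "cc_config_error")
  }
  if (is.null(names(phase_fractions)) ||
      !all(names(phase_fractions) %in% c("G1", "S", "G2M"))) {
    abort("`phase_fractions` must be named with G1/S/G2M.",
          class = "cc_config_error")
  }
  if (any(phase_fractions < 0) || abs(sum(phase_fractions) - 1) > 1e-9) {
    abort("`phase_fractions` must be non-negative and sum to 1 (within 1e-9).",
          class = "cc_config_error")
  }
  scales <- c(dna_2n_mean = dna_2n_mean,
              edu_background_mean = edu_background_mean,
              edu_rate_scale = edu_rate_scale, mcm_max_mean = mcm_max_mean,
              marker_positive_level = marker_positive_level,
              marker_negative_level = marker_negative_level)
  if (any(scales <= 0)) {
    abort("All intensity scale parameters must be strictly positive.",
          class = "cc_config_error")
  }
  cvs <- c(dna_noise_cv = dna_noise_cv, edu_background_cv = edu_background_cv,
           mcm_noise_cv = mcm_noise_cv)
  if (any(cvs < 0) || any(cvs >= 0.5)) {
    abort("CV parameters must lie in [0, 0.5).", class = "cc_config_error")
  }
  if (p21_positive_fraction_g1 < 0 || p21_positive_fraction_g1 > 1) {
    abort("`p21_positive_fraction_g1` must lie in [0, 1].",
          class = "cc_config_error")
  }
  structure(
    list(n_cells = as.integer(n_cells),
         phase_fractions = phase_fractions,
         dna_2n_mean = dna_2n_mean, dna_noise_cv = dna_noise_cv,
         edu_background_mean = edu_background_mean,
         edu_background_cv = edu_background_cv,
         edu_rate_scale = edu_rate_scale, edu_profile = edu_profile,
         mcm_max_mean = mcm_max_mean, mcm_noise_cv = mcm_noise_cv,
         mcm_g1_loading_exponent = mcm_g1_loading_exponent,
         p21_positive_fraction_g1 = p21_positive_fraction_g1,
         marker_positive_level = marker_positive_level,
         marker_negative_level = marker_negative_level,
         seed = as.integer(seed), sample = sample),
    class = "cc_config"
  )
}

#' Configuration for a thymidine-release cohort
#'
#' Describes a population synchronized at the G1/S boundary (e.g. by a
#' 24 h thymidine block) and released for `release_time_hours`. A fraction
#' `entry_fraction` of cells is competent to enter S phase on release; at
#' time `t` those cells sit at replicated fraction
#' `f = min(t / s_phase_duration_hours, 1)` plus a small per-cell jitter.
#' Non-competent cells remain G1-like. The generator emulates the
#' post-release population, not thymidine pharmacology.
#'
#' @param release_time_hours Hours since release from the block (>= 0).
#' @param s_phase_duration_hours S-phase length in hours (> 0).
#' @param entry_fraction Fraction of cells competent to enter S, in \[0, 1\].
#' @param base A [cell_cycle_config()] supplying scales, noise and seed.
#' @param f_jitter Half-width of the uniform per-cell jitter on `f`
#'   (asynchrony of entry); applied only while replication is under way.
#'
#' @return A validated list of class `cc_sync_config`.
#' @seealso [simulate_synchronized_release()]
#' @export
sync_config <- function(release_time_hours,
                        s_phase_duration_hours = 8,
                        entry_fraction = 0.65,
                        base = cell_cycle_config(),
                        f_jitter = 0.05) {
  if (release_time_hours < 0) {
    abort("`release_time_hours` must be non-negative.",
          class = "cc_config_error")
  }
  if (s_phase_duration_hours <= 0) {
    abort("`s_phase_duration_hours` must be positive.",
          class = "cc_config_error")
  }
  if (release_time_hours > 2 * s_phase_duration_hours) {
    abort("`release_time_hours` exceeds the generator validity range (2x S duration).",
          class = "cc_config_error")
  }
  if (entry_fraction < 0 || entry_fraction > 1) {
    abort("`entry_fraction` must lie in [0, 1].", class = "cc_config_error")
  }
  stopifnot(inherits(base, "cc_config"))
  structure(
    list(release_time_hours = release_time_hours,
         s_phase_duration_hours = s_phase_duration_hours,
         entry_fraction = entry_fraction, base = base, f_jitter = f_jitter),
    class = "cc_sync_config"
  )
}

#' Configuration for a simulated kinase-inhibitor screen plate
#'
#' Emulates the structure of a viability screen run in two (or more) arms —
#' e.g. a non-targeting control versus a knockdown — with per-arm blank and
#' vehicle (DMSO) wells and replicated compound wells. Planted per-compound
#' log2 viability shifts are the ground truth recovered downstream.
#'
#' @param n_compounds Number of compounds.
#' @param arms Character vector of arm labels.
#' @param n_replicates Replicate wells per compound per arm.
#' @param n_vehicle_wells,n_blank_wells Vehicle and blank wells per arm.
#' @param baseline_signal Mean raw fluorescence of an untreated (vehicle)
#'   well after growth.
#' @param blank_signal Mean raw fluorescence of a cell-free blank well;
#'   must be below `baseline_signal`.
#' @param well_noise_cv Multiplicative well noise CV in \[0, 0.5).
#' @param planted_effects Data frame with columns `compound`, `arm`,
#'   `log2_shift` (missing pairs shift 0), or `NULL` for no effects.
#' @param seed Integer seed.
#'
#' @return A validated list of class `cc_screen_config`.
#' @seealso [simulate_screen_plate()]
#' @export
screen_config <- function(n_compounds = 160,
                          arms = c("control", "knockdown"),
                          n_replicates = 2,
                          n_vehicle_wells = 8,
                          n_blank_wells = 4,
                          baseline_signal = 10000,
                          blank_signal = 500,
                          well_noise_cv = 0.05,
                          planted_effects = NULL,
                          seed = 1L) {
  if (blank_signal < 0 || blank_signal >= baseline_signal) {
    abort("`blank_signal` must be non-negative and below `baseline_signal`.",
          class = "cc_config_error")
  }
  if (well_noise_cv < 0 || well_noise_cv >= 0.5) {
    abort("`well_noise_cv` must lie in [0, 0.5).", class = "cc_config_error")
  }
  if (n_vehicle_wells < 2 || n_blank_wells < 1) {
    abort("Need >= 2 vehicle wells and >= 1 blank well per arm.",
          class = "cc_config_error")
  }
  if (n_replicates < 1 || n_compounds < 1 || length(arms) < 1) {
    abort("Counts must be positive.", class = "cc_config_error")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- tibble::as_tibble(planted_effects)
    need <- c("compound", "arm", "log2_shift")
    if (!all(need %in% names(planted_effects))) {
      abort("`planted_effects` needs columns compound, arm, log2_shift.",
            class = "cc_config_error")
    }
  }
  structure(
    list(n_compounds = as.integer(n_compounds), arms = arms,
         n_replicates = as.integer(n_replicates),
         n_vehicle_wells = as.integer(n_vehicle_wells),
         n_blank_wells = as.integer(n_blank_wells),
         baseline_signal = baseline_signal, blank_signal = blank_signal,
         well_noise_cv = well_noise_cv, planted_effects = planted_effects,
         seed = as.integer(seed)),
    class = "cc_screen_config"
  )
}

#' Configuration for a synthetic promoter-window set
#'
#' Generates i.i.d.-background promoter windows (default 1101 nt, the span
#' from 1000 bases upstream to 100 bases downstream of a TSS, both ends
#' inclusive) with a known number of motif copies planted per sequence at
#' recorded, non-overlapping offsets.
#'
#' @param n_sequences Number of windows.
#' @param window_length Window length in bases (default 1101).
#' @param gc_fraction Background GC content in (0, 1).
#' @param planted_motif DNA string over A/C/G/T to plant.
#' @param planted_per_sequence Integer vector (recycled to `n_sequences`)
#'   of copies to plant per sequence.
#' @param seed Integer seed.
#'
#' @return A validated list of class `cc_promoter_config`.
#' @seealso [generate_promoter_set()]
#' @export
promoter_set_config <- function(n_sequences = 100,
                                window_length = 1101,
                                gc_fraction = 0.5,
                                planted_motif = "TCACGTGA",
                                planted_per_sequence = 0,
                                seed = 1L) {
  if (!grepl("^[ACGT]+$", planted_motif)) {
    abort("`planted_motif` must be a non-empty string over A/C/G/T.",
          class = "cc_config_error")
  }
  if (nchar(planted_motif) > window_length) {
    abort("`planted_motif` longer than `window_length`.",
          class = "cc_config_error")
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    abort("`gc_fraction` must lie in (0, 1).", class = "cc_config_error")
  }
  planted <- as.integer(rep_len(planted_per_sequence, n_sequences))
  if (any(planted < 0)) {
    abort("`planted_per_sequence` must be non-negative.",
          class = "cc_config_error")
  }
  if (any(planted * nchar(planted_motif) > window_length)) {
    abort("Too many planted copies for the window length.",
          class = "cc_config_error")
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         window_length = as.integer(window_length),
         gc_fraction = gc_fraction, planted_motif = planted_motif,
         planted_per_sequence = planted, seed = as.integer(seed)),
    class = "cc_promoter_config"
  )
}
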