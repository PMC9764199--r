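# EdU incorporation rate as a function of replicated fraction f in [0, 1].
# "trapezoid": linear ramp on [0, 0.1], flat 1 on [0.1, 0.9], ramp down on
# [0.9, 1] — early and late S cells incorporate less per unit time.
edu_rate_profile <- function(f, profile) {
  switch(profile,
    flat = rep(1, length(f)),
    trapezoid = pmin(1, pmin(f, 1 - f) / 0.1),
    abort(paste0("Unknown EdU profile: ", profile))
  )
}

# Render observable intensities for cells with known phase and progress.
# `phase` in {G1, S, G2M}; `u` is G1 progress (loading) or S replicated
# fraction f; `edu_on` marks cells actively incorporating EdU. The draw
# order is fixed so that different generators sharing a seed produce
# identical streams for identical upstream draws.
render_cells <- function(cfg, phase, u, edu_on) {
  n <- length(phase)
  f <- ifelse(phase == "S", u, ifelse(phase == "G2M", 1, 0))
  true_dna <- cfg$dna_2n_mean * (1 + f)
  true_mcm <- ifelse(
    phase == "G1",
    pmax(cfg$mcm_max_mean * u^cfg$mcm_g1_loading_exponent,
         cfg$marker_negative_level),
    ifelse(phase == "S", cfg$mcm_max_mean * (1 - f),
           cfg$marker_negative_level)
  )
  rate <- ifelse(edu_on,
                 edu_rate_profile(f, cfg$edu_profile) * cfg$edu_rate_scale,
                 0)

  dna_total <- true_dna * lnoise(n, cfg$dna_noise_cv)
  edu_bg <- rlnorm_cv(n, cfg$edu_background_mean, cfg$edu_background_cv)
  edu_sig <- rate * lnoise(n, cfg$edu_background_cv)
  mcm2 <- true_mcm * lnoise(n, cfg$mcm_noise_cv)
  p21_state <- runif(n) < cfg$p21_positive_fraction_g1 & phase == "G1"
  true_p21 <- ifelse(p21_state, cfg$marker_positive_level,
                     cfg$marker_negative_level)
  p21 <- true_p21 * lnoise(n, cfg$mcm_noise_cv)

  tibble::tibble(
    sample = cfg$sample,
    dna_total = dna_total,
    edu_total = edu_bg + edu_sig,
    mcm2 = mcm2,
    p21 = p21,
    truth_phase = phase,
    truth_u = u,
    truth_f = ifelse(phase == "S", f, NA_real_),
    truth_dna = true_dna,
    truth_edu_rate = rate,
    truth_mcm = true_mcm,
    truth_p21_positive = p21_state
  )
}

#' Simulate an asynchronous single-cell cytometry table
#'
#' Draws each nucleus a cell-cycle phase from the configured mixture and a
#' within-phase progress `u ~ Uniform(0, 1)`, then renders observable
#' integrated intensities: DNA content (2N in G1, `2N * (1 + f)` with
#' `f = u` through S, 4N in G2/M) under multiplicative lognormal noise;
#' EdU as lognormal background plus, in S cells, an incorporation signal
#' shaped by the rate profile; chromatin-bound MCM2 loading through G1
#' (`u^exponent`), unloading through S in proportion to replicated
#' fraction, and at background in G2/M; and p21 positive in a configured
#' fraction of G1 cells only.
#'
#' Ground-truth columns are emitted with the `truth_` prefix. They exist so
#' tests can score recovery; gating and marker operations never read them.
#'
#' @param config A [cell_cycle_config()].
#' @return A tibble with one row per nucleus: `sample`, `dna_total`,
#'   `edu_total`, `mcm2`, `p21` plus `truth_*` ground-truth columns.
#' @examples
#' cells <- simulate_population(cell_cycle_config(n_cells = 1000, seed = 7))
#' dplyr::count(cells, truth_phase)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "cc_config"))
  if (config$n_cells < 100) {
    warn("Fewer than 100 cells: downstream density-based gating is unreliable.")
  }
  set.seed(config$seed)
  fr <- config$phase_fractions[config$phase_fractions > 0]
  cuts <- cumsum(fr)
  r <- runif(config$n_cells)
  phase <- names(fr)[findInterval(r, c(0, head(cuts, -1)))]
  u <- runif(config$n_cells)
  render_cells(config, phase, u, edu_on = phase == "S")
}

#' Simulate a synchronized thymidine-release cohort
#'
#' Cells are released from a G1/S block at time 0. A competent fraction
#' enters S and advances to replicated fraction
#' `f = min(t / s_phase_duration_hours, 1)` (plus small per-cell jitter
#' while replication is under way); competent cells incorporate EdU while
#' `0 < f < 1`, sit at 2N DNA with background EdU at `t = 0`, and reach 4N
#' with background EdU once replication completes. Non-competent cells
#' remain G1-like. With `entry_fraction = 0` the output is identical to a
#' pure-G1 [simulate_population()] call at the same base config and seed.
#'
#' @param config A [sync_config()].
#' @return A tibble as in [simulate_population()], plus `truth_competent`.
#' @export
simulate_synchronized_release <- function(config) {
  stopifnot(inherits(config, "cc_sync_config"))
  cfg <- config$base
  set.seed(cfg$seed)
  n <- cfg$n_cells
  competent <- runif(n) < config$entry_fraction
  u <- runif(n)

  f_base <- min(config$release_time_hours / config$s_phase_duration_hours, 1)
  if (f_base <= 0) {
    f <- rep(0, n)
  } else if (f_base >= 1) {
    f <- rep(1, n)
  } else {
    f <- clamp(f_base + config$f_jitter * (2 * u - 1), 0, 1)
  }

  phase <- ifelse(!competent, "G1",
                  ifelse(f <= 0, "G1", ifelse(f >= 1, "G2M", "S")))
  prog <- ifelse(competent, f, u)
  edu_on <- competent & f > 0 & f < 1
  out <- render_cells(cfg, phase, prog, edu_on)
  out$truth_competent <- competent
  out
}

#' Simulate a viability screen plate
#'
#' Emits one plate per arm with blank, vehicle and compound wells. A
#' well's fluorescence is assay background plus a cell-derived component:
#' blank wells read `blank_signal`, vehicle wells `blank_signal +
#' (baseline_signal - blank_signal)`, and compound wells scale the
#' cell-derived component by `2^shift`, where `shift` is the planted
#' per-arm log2 viability effect (0 where unplanted). Lognormal well
#' noise multiplies the cell-derived component (the background for
#' blanks), so blank-corrected log2 relative viability recovers the
#' planted shift exactly in the zero-noise limit.
#'
#' @param config A [screen_config()].
#' @return A tibble with columns `plate`, `well`, `role`, `arm`,
#'   `compound`, `replicate`, `signal`, `truth_log2_shift`.
#' @export
simulate_screen_plate <- function(config) {
  stopifnot(inherits(config, "cc_screen_config"))
  set.seed(config$seed)
  compounds <- sprintf("C%03d", seq_len(config$n_compounds))

  layout <- purrr::map_dfr(config$arms, function(arm) {
    dplyr::bind_rows(
      tibble::tibble(role = "blank", arm = arm,
                     compound = NA_character_,
                     replicate = seq_len(config$n_blank_wells)),
      tibble::tibble(role = "vehicle", arm = arm,
                     compound = NA_character_,
                     replicate = seq_len(config$n_vehicle_wells)),
      tidyr::expand_grid(compound = compounds,
                         replicate = seq_len(config$n_replicates)) |>
        dplyr::mutate(role = "compound", arm = arm, .before = 1)
    )
  })

  shift <- rep(0, nrow(layout))
  if (!is.null(config$planted_effects)) {
    key <- paste(layout$compound, layout$arm)
    eff <- config$planted_effects
    idx <- match(key, paste(eff$compound, eff$arm))
    shift <- ifelse(is.na(idx), 0, eff$log2_shift[idx])
    shift[layout$role != "compound"] <- 0
  }

  cell_component <- (config$baseline_signal - config$blank_signal) *
    2^shift
  noisy <- ifelse(layout$role == "blank", config$blank_signal,
                  cell_component)
  offset <- ifelse(layout$role == "blank", 0, config$blank_signal)
  layout |>
    dplyr::mutate(
      plate = paste0("P_", .data$arm),
      well = sprintf("W%03d", dplyr::row_number()),
      signal = offset + noisy * lnoise(dplyr::n(), config$well_noise_cv),
      truth_log2_shift = shift
    ) |>
    dplyr::select("plate", "well", "role", "arm", "compound",
                  "replicate", "signal", "truth_log2_shift")
}

#' Generate a synthetic promoter-window set with a planted-motif ledger
#'
#' Background bases are i.i.d. at the configured GC fraction; the requested
#' number of motif copies is planted per sequence at uniformly drawn,
#' mutually non-overlapping offsets, every placement recorded in a ledger.
#'
#' @param config A [promoter_set_config()].
#' @return A list with `sequences` (tibble `seq_id`, `sequence`) and
#'   `ledger` (tibble `seq_id`, `offset` 0-based, `strand`).
#' @seealso [write_fasta()] to emit the set as FASTA.
#' @export
generate_promoter_set <- function(config) {
  stopifnot(inherits(config, "cc_promoter_config"))
  set.seed(config$seed)
  gc <- config$gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  motif <- config$planted_motif
  mlen <- nchar(motif)
  L <- config$window_length

  ledgers <- vector("list", config$n_sequences)
  seqs <- character(config$n_sequences)
  for (i in seq_len(config$n_sequences)) {
    chars <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
    k <- config$planted_per_sequence[i]
    offsets <- integer(0)
    while (length(offsets) < k) {
      cand <- sample.int(L - mlen + 1, 1L) - 1L
      if (!any(abs(cand - offsets) < mlen)) offsets <- c(offsets, cand)
    }
    for (off in offsets) {
      chars[(off + 1):(off + mlen)] <- strsplit(motif, "")[[1]]
    }
    seqs[i] <- paste(chars, collapse = "")
    if (k > 0) {
      ledgers[[i]] <- tibble::tibble(
        seq_id = sprintf("seq_%04d", i),
        offset = sort(offsets), strand = "+"
      )
    }
  }
  ledger <- dplyr::bind_rows(purrr::compact(ledgers))
  if (nrow(ledger) == 0) {
    ledger <- tibble::tibble(seq_id = character(), offset = integer(),
                             strand = character())
  }
  list(
    sequences = tibble::tibble(seq_id = sprintf("seq_%04d",
                                                seq_len(config$n_sequences)),
                               sequence = seqs),
    ledger = ledger
  )
}
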