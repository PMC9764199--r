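test_that("identical config and seed give bit-identical output for every generator", {
  cfg <- cell_cycle_config(n_cells = 500, seed = 42)
  expect_identical(simulate_population(cfg), simulate_population(cfg))

  sc <- sync_config(2, base = cell_cycle_config(n_cells = 500, seed = 42))
  expect_identical(simulate_synchronized_release(sc),
                   simulate_synchronized_release(sc))

  pc <- screen_config(n_compounds = 10, seed = 42)
  expect_identical(simulate_screen_plate(pc), simulate_screen_plate(pc))

  mc <- promoter_set_config(n_sequences = 5, planted_per_sequence = 1,
                            seed = 42)
  expect_identical(generate_promoter_set(mc), generate_promoter_set(mc))
})

test_that("noiseless pure-G1 population is exactly at the configured means", {
  cfg <- cell_cycle_config(n_cells = 200, phase_fractions = c(G1 = 1),
                           dna_noise_cv = 0, edu_background_cv = 0,
                           mcm_noise_cv = 0, seed = 1)
  cells <- suppressWarnings(simulate_population(cfg))
  expect_equal(cells$dna_total, rep(cfg$dna_2n_mean, 200))
  expect_equal(cells$edu_total, rep(cfg$edu_background_mean, 200))
  expect_true(all(cells$truth_phase == "G1"))
})

test_that("generated phases follow the configured multinomial with unbiased G1 DNA", {
  cfg <- cell_cycle_config(n_cells = 6000,
                           phase_fractions = c(G1 = 0.5, S = 0.3, G2M = 0.2),
                           seed = 7)
  cells <- simulate_population(cfg)
  counts <- table(factor(cells$truth_phase, c("G1", "S", "G2M")))
  # oracle: the truth labels must themselves pass a goodness-of-fit test
  gof <- chisq.test(counts, p = c(0.5, 0.3, 0.2))
  expect_gt(gof$p.value, 0.001)

  g1 <- cells$dna_total[cells$truth_phase == "G1"]
  sem <- sd(g1) / sqrt(length(g1))
  expect_lt(abs(mean(g1) - cfg$dna_2n_mean), 3 * sem)
})

test_that("phase counts pass chi-square goodness of fit in at least 19 of 20 seeds", {
  fails <- 0L
  for (s in 1:20) {
    cells <- simulate_population(cell_cycle_config(n_cells = 6000, seed = s))
    counts <- table(factor(cells$truth_phase, c("G1", "S", "G2M")))
    p <- chisq.test(counts, p = c(0.5, 0.3, 0.2))$p.value
    if (p <= 0.001) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("true DNA rises and true MCM falls strictly with replicated fraction", {
  cells <- simulate_population(cell_cycle_config(n_cells = 4000, seed = 3))
  s <- cells[cells$truth_phase == "S", ]
  o <- order(s$truth_f)
  expect_true(all(diff(s$truth_dna[o]) > 0))
  expect_true(all(diff(s$truth_mcm[o]) < 0))
})

test_that("release with no competent cells reproduces a pure-G1 population draw for draw", {
  base <- cell_cycle_config(n_cells = 500, phase_fractions = c(G1 = 1),
                            seed = 9)
  rel <- simulate_synchronized_release(
    sync_config(1, entry_fraction = 0, base = base))
  pop <- simulate_population(base)
  for (col in c("dna_total", "edu_total", "mcm2", "p21", "truth_phase")) {
    expect_identical(rel[[col]], pop[[col]])
  }
  expect_false(any(rel$truth_competent))
})

test_that("mid-S release has an EdU-positive fraction matching the competent fraction", {
  base <- cell_cycle_config(n_cells = 6000, seed = 11)
  rel <- simulate_synchronized_release(
    sync_config(2, s_phase_duration_hours = 8, entry_fraction = 0.65,
                base = base))
  # the EdU-incorporating cells are exactly the competent ones
  expect_identical(rel$truth_edu_rate > 0, rel$truth_competent)
  se <- sqrt(0.65 * 0.35 / 6000)
  expect_lt(abs(mean(rel$truth_competent) - 0.65), 3 * se)
  # observably: signal is far above background for competent cells
  pos <- rel$edu_total > 5 * base$edu_background_mean
  expect_lt(abs(mean(pos) - mean(rel$truth_competent)), 0.02)
})

test_that("release at or beyond one S duration leaves competent cells 4N with background EdU", {
  base <- cell_cycle_config(n_cells = 1000, dna_noise_cv = 0,
                            edu_background_cv = 0, seed = 4)
  rel <- simulate_synchronized_release(
    sync_config(8, s_phase_duration_hours = 8, entry_fraction = 0.5,
                base = base))
  comp <- rel[rel$truth_competent, ]
  expect_equal(comp$dna_total, rep(2 * base$dna_2n_mean, nrow(comp)))
  expect_equal(comp$edu_total, rep(base$edu_background_mean, nrow(comp)))
  expect_true(all(comp$truth_phase == "G2M"))
})

test_that("negative release time is rejected", {
  expect_error(sync_config(-1), class = "cc_config_error")
})

test_that("noiseless screen plates carry planted shifts exactly", {
  cfg0 <- screen_config(n_compounds = 5, well_noise_cv = 0, seed = 1)
  pl0 <- simulate_screen_plate(cfg0)
  veh <- mean(pl0$signal[pl0$role == "vehicle" & pl0$arm == "control"])
  expect_equal(pl0$signal[pl0$role == "compound" & pl0$arm == "control"],
               rep(veh, 10))

  eff <- tibble::tibble(compound = "C002", arm = "control", log2_shift = -1)
  cfg1 <- screen_config(n_compounds = 5, well_noise_cv = 0,
                        planted_effects = eff, seed = 1)
  nz <- normalize_screen(simulate_screen_plate(cfg1))
  hit <- nz[!is.na(nz$compound) & nz$compound == "C002" &
              nz$arm == "control", ]
  expect_equal(hit$log2_rel_viability, rep(-1, nrow(hit)))
})

test_that("noisy screen plate recovers planted shifts within sampling error", {
  eff <- tibble::tibble(compound = c("C010", "C020"),
                        arm = "knockdown", log2_shift = c(-1.5, 0.8))
  cfg <- screen_config(n_compounds = 160, well_noise_cv = 0.05,
                       planted_effects = eff, seed = 11)
  nz <- suppressMessages(normalize_screen(simulate_screen_plate(cfg)))
  means <- nz |>
    dplyr::filter(.data$role == "compound") |>
    dplyr::group_by(.data$compound, .data$arm) |>
    dplyr::summarise(m = mean(.data$log2_rel_viability),
                     truth = .data$truth_log2_shift[1], .groups = "drop")
  # known noise model: sd of a log2 well value, mean of 2 replicates
  sd_mean <- sqrt(log1p(0.05^2)) / log(2) / sqrt(2)
  within <- abs(means$m - means$truth) <= 3 * sd_mean
  expect_gte(mean(within), 0.98)
  planted <- means[means$compound == "C010" & means$arm == "knockdown", ]
  expect_lt(abs(planted$m - (-1.5)), 3 * sd_mean)
})

test_that("every planted motif copy is recovered by a naive scan of the sequences", {
  cfg <- promoter_set_config(n_sequences = 30,
                             planted_per_sequence = c(0, 1, 2, 3), seed = 5)
  ps <- generate_promoter_set(cfg)
  found <- do.call(rbind, lapply(seq_len(nrow(ps$sequences)), function(i) {
    off <- oracle_scan(ps$sequences$sequence[i], cfg$planted_motif)
    if (length(off) == 0) return(NULL)
    data.frame(seq_id = ps$sequences$seq_id[i], offset = off)
  }))
  key_planted <- paste(ps$ledger$seq_id, ps$ledger$offset)
  key_found <- paste(found$seq_id, found$offset)
  expect_true(all(key_planted %in% key_found))
})

test_that("a window as long as the motif with one planted copy IS the motif", {
  cfg <- promoter_set_config(n_sequences = 1, window_length = 8,
                             planted_per_sequence = 1, seed = 1)
  ps <- generate_promoter_set(cfg)
  expect_identical(ps$sequences$sequence, "TCACGTGA")
  expect_identical(ps$ledger$offset, 0L)
})

test_that("invalid generator configurations are rejected", {
  expect_error(cell_cycle_config(phase_fractions = c(G1 = 0.6, S = 0.3)),
               class = "cc_config_error")
  expect_error(cell_cycle_config(dna_noise_cv = 0.7),
               class = "cc_config_error")
  expect_error(cell_cycle_config(dna_2n_mean = -5),
               class = "cc_config_error")
  expect_error(screen_config(blank_signal = 2e5),
               class = "cc_config_error")
  expect_error(promoter_set_config(planted_motif = "TCACGTGX"),
               class = "cc_config_error")
  expect_error(promoter_set_config(window_length = 4,
                                   planted_motif = "TCACGTGA"),
               class = "cc_config_error")
  expect_warning(simulate_population(cell_cycle_config(n_cells = 50)),
                 "100 cells")
})
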