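two_level_table <- function(n1 = 400, n2 = 200, v1 = 2, v2 = 4) {
  tibble::tibble(sample = "s", dna_total = c(rep(v1, n1), rep(v2, n2)),
                 edu_total = 10)
}

test_that("DNA scale fitting finds noiseless 2N/4N values and imputes a missing 4N", {
  sc <- fit_dna_scale(two_level_table())
  expect_lt(abs(sc$g1_peak - 2) / 2, 0.02)
  expect_lt(abs(sc$g2_peak - 4) / 4, 0.02)
  expect_false(sc$imputed_4n)

  pure <- tibble::tibble(sample = "s", dna_total = rep(3, 600),
                         edu_total = 10)
  sc2 <- fit_dna_scale(pure)
  expect_equal(sc2$g1_peak, 3)
  expect_equal(sc2$g2_peak, 6)
  expect_true(sc2$imputed_4n)
})

test_that("DNA scale fitting errors on too few nuclei and missing columns", {
  expect_error(fit_dna_scale(two_level_table(100, 50)),
               class = "cc_insufficient_data_error")
  expect_error(fit_dna_scale(tibble::tibble(x = 1)),
               class = "cc_schema_error")
})

test_that("fitted 2N/4N peaks recover simulated means within 3 percent", {
  cells <- simulate_population(
    cell_cycle_config(n_cells = 6000, dna_2n_mean = 1000,
                      dna_noise_cv = 0.05, seed = 3))
  sc <- fit_dna_scale(cells)
  expect_lt(abs(sc$g1_peak - 1000) / 1000, 0.03)
  expect_lt(abs(sc$g2_peak - 2000) / 2000, 0.03)
  expect_true(sc$g2_peak / sc$g1_peak >= 1.7 &&
                sc$g2_peak / sc$g1_peak <= 2.3)
})

test_that("a perfectly separated bimodal EdU yields a valley threshold between the modes", {
  df <- tibble::tibble(
    sample = "s",
    dna_total = rep(c(2, 4), each = 400),
    edu_total = rep(c(10, 1000), each = 400))
  sc <- fit_dna_scale(df)
  thr <- fit_edu_threshold(df, sc)
  expect_identical(thr$method, "valley")
  expect_gt(thr$threshold, 10)
  expect_lt(thr$threshold, 1000)
})

test_that("unimodal EdU falls back to the 4N-gate 3-SD reference rule", {
  cells <- simulate_population(
    cell_cycle_config(n_cells = 6000,
                      phase_fractions = c(G1 = 0.7, G2M = 0.3), seed = 13))
  sc <- fit_dna_scale(cells)
  thr <- fit_edu_threshold(cells, sc)
  expect_identical(thr$method, "fallback_4n")
  # essentially no cell should be called EdU-positive (<= 0.3% + noise)
  expect_lt(mean(cells$edu_total > thr$threshold), 0.006)
})

test_that("unimodal EdU with an empty 4N gate is a threshold failure", {
  set.seed(8)
  df <- tibble::tibble(sample = "s", dna_total = rep(2, 600),
                       edu_total = rlnorm(600, log(50), 0.2))
  sc <- fit_dna_scale(df)  # imputes 4N at 4; no cells there
  expect_error(fit_edu_threshold(df, sc), class = "cc_fit_error")
})

test_that("EdU-positive fraction tracks the true S fraction", {
  cfg <- cell_cycle_config(n_cells = 6000, seed = 5)
  cells <- simulate_population(cfg)
  sc <- fit_dna_scale(cells)
  thr <- fit_edu_threshold(cells, sc)
  expect_lt(abs(mean(cells$edu_total > thr$threshold) - 0.3), 0.03)
})

test_that("phase assignment follows the gate geometry rule for rule", {
  m <- gating_model(g1_peak = 1000, edu_threshold = 100)
  cases <- tibble::tibble(
    sample = "s",
    dna_total = c(1000, 1000, 2000, 1600, 1100, 1149, 1500, 1501, 2100,
                  2400),
    edu_total = c(50, 200, 50, 50, 200, 200, 200, 200, 200, 50),
    expected = c("G1", "EarlyS", "G2M", "Unclassified", "EarlyS",
                 "EarlyS", "S1", "LateS", "LateS", "Unclassified"))
  out <- assign_phases(cases, m)
  expect_identical(as.character(out$phase), cases$expected)
})

test_that("the S1/late-S boundary at f = 0.5 is inclusive to S1", {
  m <- gating_model(g1_peak = 1000, edu_threshold = 100)
  out <- assign_phases(tibble::tibble(sample = "s", dna_total = 1500,
                                      edu_total = 500), m)
  expect_identical(as.character(out$phase), "S1")
})

test_that("macro-class agreement with ground truth is at least 90 percent", {
  cells <- simulate_population(cell_cycle_config(n_cells = 6000,
                                                 dna_noise_cv = 0.05,
                                                 seed = 21))
  lab <- gate_cells(cells)
  macro <- dplyr::case_when(
    lab$phase %in% c("EarlyS", "S1", "LateS") ~ "S",
    lab$phase == "Unclassified" ~ NA_character_,
    .default = as.character(lab$phase))
  ok <- !is.na(macro)
  expect_gte(mean(macro[ok] == lab$truth_phase[ok]), 0.90)
})

test_that("re-assigning phases is idempotent", {
  cells <- simulate_population(cell_cycle_config(n_cells = 2000, seed = 2))
  m <- fit_gating_model(cells)
  once <- assign_phases(cells, m)
  twice <- assign_phases(once, m)
  expect_identical(once$phase, twice$phase)
})

test_that("phase labels are invariant to a global DNA rescaling", {
  cells <- simulate_population(cell_cycle_config(n_cells = 4000, seed = 6))
  lab1 <- gate_cells(cells)
  cells2 <- dplyr::mutate(cells, dna_total = dna_total * 7.3)
  lab2 <- gate_cells(cells2)
  # exact up to floating-point jitter of cells sitting on a gate boundary
  expect_gte(mean(as.character(lab1$phase) == as.character(lab2$phase)),
             0.9995)
})

test_that("phase fractions normalise and handle pure-G1 input", {
  m <- gating_model(g1_peak = 1000, edu_threshold = 100)
  lab <- assign_phases(tibble::tibble(sample = "s",
                                      dna_total = rep(1000, 10),
                                      edu_total = rep(10, 10)), m)
  fr <- phase_fractions(lab)
  expect_equal(fr$fraction[fr$phase == "G1"], 1)
  expect_equal(sum(fr$share_total), 1, tolerance = 1e-12)
  expect_equal(s_phase_fraction(lab)$s_fraction, 0)

  mixed <- assign_phases(
    tibble::tibble(sample = "s",
                   dna_total = c(1000, 1200, 1500, 2000, 1600),
                   edu_total = c(10, 500, 500, 10, 10)), m)
  fr2 <- phase_fractions(mixed)
  expect_equal(sum(fr2$share_total), 1, tolerance = 1e-12)
  classified <- fr2[fr2$phase != "Unclassified", ]
  expect_equal(sum(classified$fraction), 1, tolerance = 1e-12)
})

test_that("a control/knockdown S-fraction difference is recovered within 3 points", {
  diffs <- sapply(1:5, function(s) {
    ctrl <- simulate_population(cell_cycle_config(
      n_cells = 6000, phase_fractions = c(G1 = 0.4, S = 0.5, G2M = 0.1),
      seed = s, sample = "control"))
    kd <- simulate_population(cell_cycle_config(
      n_cells = 6000, phase_fractions = c(G1 = 0.5, S = 0.4, G2M = 0.1),
      seed = s + 100, sample = "knockdown"))
    sf <- s_phase_fraction(gate_cells(dplyr::bind_rows(ctrl, kd)))
    sf$s_fraction[sf$sample == "control"] -
      sf$s_fraction[sf$sample == "knockdown"]
  })
  expect_true(all(abs(diffs - 0.1) < 0.03))
})

test_that("borrowed-scale gating applies one sample's model everywhere", {
  ctrl <- simulate_population(cell_cycle_config(n_cells = 3000, seed = 1,
                                                sample = "t0"))
  arrested <- simulate_population(cell_cycle_config(
    n_cells = 3000, phase_fractions = c(G1 = 0.97, S = 0.02, G2M = 0.01),
    seed = 2, sample = "t1"))
  lab <- gate_cells(dplyr::bind_rows(ctrl, arrested), borrow_scale = "t0")
  models <- attr(lab, "gating_models")
  expect_identical(models$t0$dna_scale$g1_peak,
                   models$t1$dna_scale$g1_peak)
})
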