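# cyclegate

Downstream analytics for high-content imaging cytometry of the cell
cycle, written for labs that quantify per-nucleus fluorescence with
segmentation software (e.g. CellProfiler) and then need reproducible
gating and statistics rather than one-off scripts. The package covers
the analysis chain used in origin-licensing studies of cultured cells:

* **EdU × DNA bivariate gating.** Each nucleus carries an integrated
  DNA-stain intensity and an EdU (5-ethynyl-2′-deoxyuridine)
  incorporation intensity. Cells are G1 if EdU-negative with 2N DNA, G2/M
  if EdU-negative with 4N DNA, and S-phase if EdU-positive; EdU-positive
  cells subdivide into Early S (DNA still within the 2N gate), mid-S
  ("S1", replicated fraction *f* = DNA/2N − 1 ≤ 0.5) and Late S. The 2N
  and 4N peaks are found by kernel density estimation on log DNA, and the
  EdU cut by the density valley between the background and incorporation
  modes (with a G2-referenced mean + 3 SD fallback).
* **Origin-licensing quantification.** Chromatin-bound MCM2 is loaded
  through G1 and unloaded in proportion to replicated DNA, so percent
  MCM2-positive cells per phase — thresholded against the MCM-negative
  G2/M reference — measures licensing capacity.
* **Replication-rate statistics.** Per-sample mean/median total EdU in
  S-phase cells plus the 95th percentile of total EdU, the "maximal
  replication rate" statistic (type-7 percentile convention).
* **Kinase-screen differential viability.** Plate normalization
  (blank-corrected, vehicle-referenced, log2) and a hand-authored
  empirical-Bayes moderated t per compound between two arms:
  s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), t̃ = Δ_g / (s̃_g √(1/n₁+1/n₂)),
  referred to t with d₀ + d_g df, hyper-parameters by digamma/trigamma
  moment matching, BH q-values, volcano plot.
* **CLEAR promoter-motif enrichment.** Promoter windows spanning
  −1000..+100 nt around TSSs (1101 nt, inclusive), exact overlapping
  scans for the self-reverse-complementary TFEB-binding motif
  `TCACGTGA`, and counts-based one-sided hypergeometric enrichment in
  the standard *fg%*, *bg%*, ratio, p, q schema.
* **A synthetic single-cell generator** with complete ground truth
  (phase labels, replicated fraction, true marker states, planted screen
  effects and motif placements) drives every stage, so the whole
  pipeline is testable without imaging data.

## Worked example

Simulate a control population and an under-licensed "knockdown"
(S fraction 0.30 → 0.22, peak MCM2 halved), gate, and quantify:

```r
library(cyclegate)
library(dplyr)

control <- simulate_population(cell_cycle_config(n_cells = 6000, seed = 1,
                                                 sample = "control"))
knockdown <- simulate_population(cell_cycle_config(
  n_cells = 6000, phase_fractions = c(G1 = 0.58, S = 0.22, G2M = 0.20),
  mcm_max_mean = 400, seed = 2, sample = "knockdown"))

labeled <- gate_cells(bind_rows(control, knockdown))
s_phase_fraction(labeled)
#>   sample    n_cells s_fraction
#> 1 control      5987      0.280
#> 2 knockdown    5979      0.218

glance(attr(labeled, "gating_models")$control)
#>   sample  g1_peak g2_peak imputed_4n edu_threshold edu_method     n
#> 1 control    999.   1976. FALSE               225. valley      6000
```

The fitted 2N/4N peaks sit at 999 and 1976 (configured: 1000 and 2000),
and the recovered S fractions (28.0% vs 21.8%) match the configured 0.30
vs 0.22 within sampling error. Licensing per phase, against the G2/M
negative reference:

```r
thr <- fit_positivity_threshold(labeled$mcm2, "reference_quantile",
                                reference = labeled$mcm2[labeled$phase == "G2M"])
percent_positive_by_phase(labeled, "mcm2", thr) |>
  filter(phase %in% c("G1", "EarlyS", "G2M"))
#>   sample    marker phase  n_cells percent_positive median_intensity
#> 1 control   mcm2   G1        3047           96.0              377.
#> 2 control   mcm2   EarlyS     230          100                711.
#> 3 control   mcm2   G2M       1262            1.19              19.3
#> 4 knockdown mcm2   G1        3435           92.6              194.
#> 5 knockdown mcm2   EarlyS     184          100                350.
#> 6 knockdown mcm2   G2M       1239            0.807             19.3
```

Median chromatin-bound MCM2 in G1 halves under knockdown (377 → 194)
while G2/M cells stay at background — the licensing signature. S-phase
replication-rate summary:

```r
s_phase_edu_summary(labeled)
#>   sample    n_s_cells total_edu_mean total_edu_median edu_p95
#> 1 control        1678          1894.            1875.   3087.
#> 2 knockdown      1305          1854.            1813.   3124.
```

`plot_gating(labeled)`, `plot_marker_density()` and `plot_volcano()` /
`autoplot()` provide the standard figures; `tidy()` and `glance()` give
broom-style access to fitted gating models and screen results;
`run_pipeline()` executes simulate → gate → marker → replication from a
config list or YAML file and writes TSV/CSV outputs plus a manifest.

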