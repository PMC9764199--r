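---
title: "Methods: cell-cycle gating, licensing statistics and screen analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle gating, licensing statistics and screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclegate)
library(dplyr)
```

This vignette is the package's own account of its methods: the models
behind each stage, the parameters that matter, the numerical conventions
we fixed where the field leaves them open, and what the synthetic-data
tests do and do not establish about real imaging data.

## The measurement model

The pipeline starts from per-object tables: one row per segmented
nucleus with integrated (total) fluorescence intensities — a DNA stain
(e.g. Hoechst 33342), EdU click signal, and optional marker channels
(chromatin-bound MCM2, p21, γH2A.X). Intensities are unitless totals as
emitted by object-measurement software; no pixel data enter the
pipeline. We model fluorescence noise as multiplicative lognormal.
Fluorescence is positive and right-skewed, lognormal noise keeps the 2N
and 4N DNA modes symmetric on the log scale, and in consequence *all
density estimation in the package operates on log intensities*.

## EdU × DNA gating

An asynchronous population has 2N DNA in G1, 4N in G2/M, and
intermediate content through S; an EdU pulse (default 30 min) marks
cells replicating at fixation. Gating proceeds per sample:

1. **DNA scale** (`fit_dna_scale()`): a kernel density estimate of log
   DNA (Silverman's rule-of-thumb bandwidth × a configurable multiplier,
   default 1) locates the 2N peak as the tallest mode. The 4N peak is
   the tallest mode whose ratio to the 2N peak lies in [1.7, 2.3] — the
   plausible band for a stoichiometric DNA stain; outside it the fit is
   rejected. If no mode falls in the band (pure-G1 or heavily arrested
   samples) the 4N position is imputed at exactly 2 × 2N and the result
   flagged `imputed_4n`. Gates are relative windows around each peak
   (default half-width 0.15 of the peak position, wide enough for 5% CV
   noise and narrow enough that mid-S cells fall outside both gates).
2. **EdU threshold** (`fit_edu_threshold()`): the field reports only the
   EdU-negative/positive dichotomy, so the numeric cut is our choice and
   is recorded in the output for audit. Primary method: the
   minimum-density valley between the two tallest log-EdU modes
   (background vs incorporation). Modes below 10% of the tallest mode's
   height are ignored as KDE ripple, and the valley is accepted only if
   it dips below half the lower mode — otherwise the distribution is
   treated as unimodal and the fallback applies: threshold =
   exp(mean + 3 SD) of log EdU among cells in the 4N gate, a
   G2-dominated, EdU-negative reference. The method used
   (`valley` / `fallback_4n`) is part of the gating report.
3. **Phase assignment** (`assign_phases()`): EdU-negative cells are G1
   or G2M by gate membership, and `Unclassified` when EdU-negative with
   mid-range DNA (the literature is silent on this class; we count it
   and exclude it from phase fractions rather than forcing it into a
   phase). EdU-positive cells are Early S while DNA remains at or below
   the top of the 2N gate; beyond that the replicated fraction
   `f = clamp(DNA/2N − 1, 0, 1)` splits mid-S ("S1", `f ≤ 0.5`,
   boundary inclusive — a fixed tie-break) from Late S. G2 and M are
   merged: a DNA × EdU bivariate cannot separate them.

Fitting is per sample, because arrested or released samples have
distorted histograms; `gate_cells(borrow_scale =)` lets a release time
course borrow the t = 0 sample's model instead. Intensity normalization
upstream of the package is not assumed beyond per-sample consistency:
all gates are anchored to the sample's own fitted 2N position, which
makes phase labels invariant to any global rescaling of a sample's DNA
channel (a property the tests verify).

## Marker statistics

`fit_positivity_threshold()` offers three auditable conventions, all on
log intensity: Otsu's between-class variance cut (plateau centred, so an
empty gap between classes cuts in its middle); a two-component Gaussian
mixture cut at equal posterior; and the default for chromatin-bound
MCM2, a negative-reference quantile — the 0.99 quantile of G2/M cells,
which have unloaded MCM and provide an internal negative control.
Percent-positive is computed per phase with a strict inequality (values
equal to the threshold count negative — a fixed convention so counts
reproduce). Empty phases are reported with `n = 0` and `NA` percent,
never silently dropped or zeroed; phases under 50 cells are flagged.
Thresholds default to per-experiment (pooled) fitting with per-sample
fitting available, since nothing in common practice fixes this choice.
Per-phase density curves share one grid (pooled 1st–99th log-intensity
percentiles, 512 points) so treatments overlay, and each curve is
renormalised to integrate to 1 by the trapezoidal rule.

## Replication-rate statistics

`s_phase_edu_summary()` restricts to cells gated Early S ∪ S1 ∪ Late S
and reports mean, median and the 95th percentile of total EdU — the
maximal-replication-rate statistic. Percentiles use linear interpolation
between order statistics (R's type 7); the convention is stated because
the statistic is a reporting quantity. Summaries are not
background-subtracted by default (the gate already excludes EdU-negative
cells); `subtract_background = TRUE` subtracts the per-sample G1 median.
Total nuclear EdU intensity is used rather than per-area intensity,
matching object-level measurement tables.

## Screen analytics

`normalize_screen()` implements the standard viability normalization:
subtract the mean blank of the plate-arm, divide by the mean corrected
vehicle (DMSO) signal of the arm, log2. Wells whose corrected signal is
non-positive are flagged and excluded with a reported count. Adding any
constant to all signals of a plate-arm leaves the result unchanged.

`moderated_t_test()` is the package's own implementation of the
empirical-Bayes moderated t for small-replicate screens: per compound,
the pooled within-arm variance s²_g with d_g df shrinks toward a prior,
s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), and t̃ = Δ_g/(s̃_g√(1/n₁+1/n₂))
is referred to t with d₀ + d_g df (two-sided). Hyper-parameters are
estimated by method-of-moments on log s²_g using digamma/trigamma
identities of the scaled-F model; when the moment equation has no
positive root (observed variance spread no larger than chi-square
sampling noise) the fit falls back to a fixed d₀ = 4 with a logged
message — a deliberately conservative amount of moderation for
duplicate screens. Two checks pin the implementation down: at d₀ = 0 it
equals the ordinary pooled t exactly, and the test suite cross-checks
the hyper-parameter fit and statistics against limma on the same
matrix. Replicate means per arm define the reported per-arm viability;
compounds present in only one arm are excluded with a logged reason.
Direction is reported via the sign of Δ (both sensitization and
resistance are of interest), and multiplicity is handled by
Benjamini–Hochberg q-values (`bh_adjust()`, delegating to
`stats::p.adjust`).

## Promoter-motif enrichment

Promoter windows span −1000..+100 nt around the TSS with both ends
inclusive — 1101 nt; inclusivity is our fixed reading of the
conventional "between −1000 and +100" phrasing. Internally coordinates
are 0-based; TSS tables are accepted 1-based by default (the common
gene-table convention) with conversion at the reader. Minus-strand
windows are reverse-complemented so every window reads
promoter-to-downstream. Windows truncated at a sequence end are emitted
with a flag.

`scan_motif()` counts exact overlapping matches (shift-by-one); the
CLEAR motif `TCACGTGA` cannot overlap itself non-trivially and is its
own reverse complement, so single-strand scanning is complete for it —
`both_strands = TRUE` covers non-palindromic motifs. Positions
containing `N` never match. Gene-level presence (≥ 1 hit) drives
enrichment counts, and `motif_enrichment_test()` computes the one-sided
hypergeometric tail P[X ≥ fg_with] with BH adjustment across the motifs
of one call. HOMER-style background GC-matching and autonormalization
are out of scope; the published percentage table shipped with the
package validates the ratio arithmetic, and the hypergeometric tail is
validated against exhaustive enumeration for all populations up to
size 12.

## The synthetic generator: what it emulates

`simulate_population()` draws each cell a phase from the configured
mixture and a within-phase progress u ~ U(0,1), then renders
observables:

* DNA: 2N in G1, 2N(1+f) with f = u through S, 4N in G2/M, times
  lognormal noise (default CV 0.05 — typical for integrated Hoechst).
* EdU: lognormal background (mean 50, CV 0.3) for non-replicating
  cells; S cells add `rate(f) × edu_rate_scale` (default 2000, i.e. 40×
  background at full rate). The default rate profile is a trapezoid —
  ramping over f ∈ [0, 0.1] and [0.9, 1], flat between — giving the
  realistic dim early/late-S cells that make the Early S gate
  non-trivial; a `flat` profile is available.
* MCM2: loading through G1 as `mcm_max · u^exponent` (default exponent
  1, linear loading; peak 800), unloading through S as
  `mcm_max · (1−f)`, background (20) in G2/M, CV 0.2.
* p21: positive in a configured fraction of G1 cells only (default
  0.5), at level 500 vs background 20.

Ground truth (phase, u, f, noiseless DNA/MCM, p21 state, EdU rate) is
emitted in `truth_`-prefixed columns that analysis functions never
read; they exist purely so tests can score recovery.
`simulate_synchronized_release()` reuses the same renderer for a
post-thymidine-release cohort: a competent fraction advances to
f = min(t/T_S, 1) (default T_S = 8 h, a typical S-phase length) with a
±0.05 uniform jitter for entry asynchrony, incorporating EdU only while
0 < f < 1; non-competent cells remain G1-like. With zero competence the
output is draw-for-draw identical to a pure-G1 population at the same
seed, a property the tests use. `simulate_screen_plate()` renders wells
as assay background plus a viability-proportional component scaled by
2^(planted log2 shift), so normalization recovers planted effects
exactly in the zero-noise limit. `generate_promoter_set()` produces
i.i.d.-background windows at a configured GC fraction with
non-overlapping planted motif copies recorded in a ledger. Each
generator consumes one seeded stream, so identical configs reproduce
bit-identical tables.

The generator deliberately does *not* model: replication-fork or
per-origin kinetics, thymidine pharmacology, apoptosis, doublets and
segmentation errors, spatial plate effects, or sequence composition
beyond i.i.d. background. Passing recovery tests therefore establish
that the estimators are correct under the stated noise model at
realistic parameter values — not that they are robust to every artifact
of real imaging data; the auditable method flags (imputed 4N, fallback
thresholds, truncation, low-n) are the package's handle on such data.

## Numerical choices and degenerate inputs

* KDE bandwidths: Silverman's rule with a multiplier; marker densities
  apply an absolute floor of 0.01 log units so near-constant inputs
  remain representable as a sharp mode. Degenerate constant DNA input
  short-circuits to an exact peak with imputed 4N.
* Mode detection: sign changes of the density's first difference;
  sub-10% modes discarded; valley acceptance requires a dip below half
  the lower mode.
* Boundaries: S1/LateS split at f = 0.5 inclusive to S1;
  marker positivity strict (`>`); percentile type 7; BH with enforced
  monotonicity (via `p.adjust`).
* CSV output writes doubles at 17 significant digits and the reader
  parses with correctly rounded `strtod`, so tables round-trip bit for
  bit; rows with missing or negative intensities are dropped with a
  reported count.

## Problem sizes used by the tests

The recovery suites run at the package's reference conditions: n = 6000
cells per sample (20 seeds for gating recovery, 5 for release and
rate-ratio checks), 160–200 compounds with duplicate wells (50 seeds
for null calibration, 20 for hit ranking), 1000 windows for scan-oracle
equality and 10,000 for chance-rate calibration. These sizes give the
binomial/Poisson standard errors that the stated tolerances (±3
percentage points, 3 SE bands) are calibrated to.

## Known limitations

Doublet exclusion, mitotic-cell identification (e.g. by phospho-H3),
cross-plate batch correction, dose–response fitting, foci counting and
PWM/log-odds motif scanning are out of scope. The EdU pulse length is
recorded but not modelled: rate statistics compare samples only under a
common pulse. The moderated t assumes two arms per contrast; multi-arm
designs require one call per contrast.
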