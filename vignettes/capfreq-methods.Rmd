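---
title: "Frequency-specific coactivation pattern analysis with capfreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific coactivation pattern analysis with capfreq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capfreq)
library(dplyr)
```

## The model

Resting-state BOLD activity can be described as a sequence of recurring
whole-brain *coactivation patterns* (CAPs): instead of averaging
connectivity over a scan, each individual fMRI frame (one volume, here a
vector of 408 ROI values) is treated as a sample of the brain's momentary
configuration, and frames are clustered into a small number of states. A
subject's scan then becomes a categorical time series of state labels, and
its temporal structure — how long states last, how often they recur, how
they hand over to one another — carries information that static
connectivity discards.

`capfreq` resolves this analysis by frequency band. The BOLD signal between
0.01 and 0.25 Hz is decomposed into the typical low-frequency range
(0.01–0.08 Hz) and four canonical sub-bands — slow-5 (0.01–0.027), slow-4
(0.027–0.073), slow-3 (0.073–0.198) and slow-2 (0.198–0.25 Hz) — and the
whole state analysis is repeated per band. The working hypothesis this
machinery serves: the *spatial* topography of the states is largely
preserved across bands, while their *temporal* dynamics are strongly
band-dependent, and clinical group differences (the package's vocabulary
uses an HC/SZ contrast) concentrate in the dynamics.

The pipeline:

1. **Band decomposition** (`bandpass()`): per-ROI zero-phase Butterworth
   filtering (two second-order sections applied forward and backward via
   `signal::filtfilt`). Zero phase matters because the unit of analysis is
   the individual frame: a causal filter would lag every state transition.
   Columns are linearly detrended first. The filter family is a design
   choice, not something the analysis depends on: any linear-phase
   band-pass with adequate roll-off gives equivalent states. At TR = 2 s
   the slow-2 band's upper edge sits exactly at Nyquist, where a band-pass
   design degenerates; that band is implemented as a high-pass of the same
   order.
2. **Normalization** (`zscore_rois()`): each ROI time course to mean 0 and
   unit variance (population SD, dividing by *T*; the convention is fixed
   so worked examples are exact). |Z| then reads as deviation from that
   region's own baseline.
3. **State discovery** (`cluster_caps()`): k-means over all frames pooled
   from the *reference* (control) cohort only. Frames are centred and
   scaled to unit norm before clustering, so squared Euclidean distance is
   proportional to 1 − Pearson r — the same spatial-similarity measure
   used for everything else (frame assignment, alignment). Using one
   geometry throughout is deliberate: training and projection must agree
   on what "similar" means. Initialization is seeded k-means++, 10
   restarts, best total within-cluster cost kept; a restart that collapses
   a cluster is re-seeded and logged. K defaults to 6, and
   `silhouette_curve()` provides the standard data-driven check (mean
   silhouette width under the 1 − r distance across candidate K).
4. **Z-maps and projection** (`compute_zmaps()`, `assign_frames()`): each
   state's map is the member-frame mean divided by the member-frame SD,
   ROI-wise. Frames of subjects outside the reference cohort — patients,
   or held-out controls — are assigned to the state with the highest
   Pearson correlation; exact ties (measure-zero in practice) go to the
   lowest state index with a message.
5. **Cross-band alignment** (`align_capsets()`): states discovered
   independently per band are matched by the assignment problem on the
   1 − r cost, solved with the Hungarian method (`clue::solve_LSAP`); the
   test suite checks the solver against exhaustive enumeration of all 6!
   bijections.
6. **Dynamics** (`cohort_dynamics()`): per subject and state, fraction of
   time (N_A/N), episode counts (maximal runs), persistence (mean run
   length × TR, seconds) and the transition probability matrix
   (N_A→B/N_A), whose diagonal is the resilience. Runs truncated at scan
   boundaries count in full — with that convention the identity
   fraction · T · TR = counts · persistence holds *exactly* and is
   asserted, not approximated. Absent states get NA persistence (never an
   artificial 0) and drop out of group means; transition denominators
   exclude the final frame, so defined rows sum to 1 exactly. Metrics are
   always computed within subject and then aggregated; concatenating
   subjects would fabricate transitions at the seams.
7. **Statistics** (`repeated_measures_anova()`, `mixed_anova()`,
   `paired_t()`, `two_sample_t_adjusted()`, `permutation_test()`,
   `chi_square_table()`, `bonferroni()`, `fdr_bh()`): the battery for
   band effects (within-subject), group-by-band interactions (split-plot
   ANOVA with age/sex/mean-FD as fixed nuisance covariates in the
   between-subject stratum), post-hoc contrasts, and multiplicity control.
   With two within-subject levels the split-plot ANOVA and a
   random-intercept mixed model coincide, which is why the simpler
   `aov`-based implementation is used. The covariate-adjusted two-sample
   test is the group-coefficient t in `lm(outcome ~ group + covariates)`;
   with no covariates the function deliberately reduces to Welch's t.
8. **Classification** (`build_feature_matrix()`, `f_score()`, `lopo_cv()`,
   `holdout_experiment()`, `consensus_features()`): a subject's spatial
   features are, per state, the mean of their z-scored frames assigned to
   that state — K × R = 2448 values for one band at K = 6, R = 408
   (a mean/SD variant sits behind `subject_zscore`). Features are ranked
   by F-score *inside each training fold*, the feature count swept over a
   grid (default 20–1500 by 20) and the smallest count achieving the
   maximal accuracy reported; the SVM is linear with C = 1 (`e1071`,
   libsvm). Leave-one-pair-out CV holds out one patient plus one control
   per fold; the hold-out experiment additionally re-defines the CAPs on a
   disjoint control subset each repetition, which is the honest design
   when the same controls would otherwise both define the states and be
   classified. Stable features are extracted by the two-stage 80%/80%
   consensus rule.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| TR | 2.0 | s | sampling interval of the acquisitions emulated |
| frames per subject | 235 | frames | 240 acquired minus 5 equilibration |
| K (states) | 6 | — | silhouette-supported; three opposite-sign pairs |
| k-means restarts | 10 | — | stability of the best-cost solution |
| band edges | see `built_in_bands()` | Hz | canonical slow-band taxonomy |
| SVM C | 1 | — | standard linear-SVM default |
| feature grid | 20–1500 by 20 | features | selection sweep |
| consensus thresholds | 0.80 / 0.80 | proportion | within/across repetitions |

## What the generator emulates — and what it does not

`simulate_cohort()` produces data in which every downstream quantity has a
known ground truth: K/2 base spatial patterns with disjoint active ROI
blocks (a coarse stand-in for large-scale network structure), each paired
with its exact negation — so the planted between-state correlation matrix
contains three −1 pairs; first-order Markov label sequences whose
self-transition probability 1 − 1/dwell gives geometric run lengths with
mean exactly `dwell_frames` (the closed form every dwell oracle uses);
white Gaussian ROI noise; and demographics with overlapping age
distributions, balanced sex, and log-normal (right-skewed) mean framewise
displacement. Group effects are planted on the *dynamics* (per-state dwell
multipliers, occupancy shifts), never on the template shapes.

Band-limited cohorts (`simulate_multiband_cohort()`) filter the *noise*
component to the band and plant band-specific dwell (defaults 6, 2.5, 1.3,
1.1 frames from slow-5 to slow-2, mirroring the qualitative slowing of
state dynamics toward lower bands). The state signal itself is a square
wave and is left unfiltered: passing it through the band filter would
destroy the run-length ground truth the recovery tests are scored against,
so simulated cohorts enter the pipeline at the z-scoring step. The
filtering stage is instead validated directly on signals with known
spectra (sines, white noise, DC).

What the generator does *not* emulate: hemodynamic convolution, spatially
correlated or physiological noise, motion artefacts beyond a scalar FD
covariate, anatomically realistic network geometry, and any within-state
spatial variability of the patterns. Passing recovery tests therefore
demonstrates that the *computational chain* is correct and unbiased at
realistic SNR — not that real acquisitions will be as separable; real CAP
analyses face overlapping states and far lower effective SNR.

## Numerical choices and degenerate inputs

- Population-SD z-scoring throughout (frames and Z-maps); documented so
  hand-worked examples match to machine precision.
- Constant (dead) ROIs, zero-variance frames, states with < 2 member
  frames, missing table cells and zero contingency margins are hard
  errors, never silent repairs.
- Assignment ties break to the lowest state index, with a message.
- The permutation test uses the add-one estimator, so p is never 0.
- The Hungarian cost is `max(sim) − sim`; adding a constant to every
  similarity provably cannot change the optimal bijection, and a test
  asserts it.
- Empty clusters re-seed the affected k-means restart rather than
  silently returning fewer states.

## Problem sizes used in the tests

The recovery suite runs the full default cohort (20 + 20 subjects × 235
frames × 408 ROIs, plus four band-specific cohorts of the same size);
calibration studies use 1000 null replicates per test; classification
checks use up to 100 pairs with reduced feature grids. The hold-out
experiment's unit tests run scaled-down repetition counts (3 × 2 instead
of the 100 × 10 a full study would use) — the experiment's logic is
identical at any repetition count, which is itself a config parameter.

## Known limitations

- The center-frequency normalization of persistence is implemented as
  persistence × band-center (cycles per episode); other normalizations
  (e.g. per-band period ratios) are possible and would rescale, not
  reorder, band comparisons.
- The split-plot ANOVA covers the two-band, two-group design it is used
  for; designs with more within-subject levels would need sphericity
  handling that is deliberately out of scope.
- `match_controls()` uses greedy nearest-age matching within sex; it is
  not globally optimal (optimal pair matching would need a full
  assignment solve over ages) but is the common practice it emulates.
- Counts are per-scan totals, not rates; scans of unequal length should
  be compared via fraction of time or persistence instead.
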