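---
title: "PESI-MS tissue classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PESI-MS tissue classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pesiclass` turns raw 2-minute probe-electrospray (PESI) acquisitions of
liver-tissue homogenates into per-specimen tumour/non-tumour verdicts.  This
vignette documents the statistical model behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## The measurement and its preprocessing

A PESI acquisition is a sequence of full-scan continuum spectra over
*m/z* 10–2000 Da recorded for 120 s.  Ionization from a sampling needle is
unstable over minutes: signal degrades toward the end of a run as the needle
fouls.  The analysis therefore divides each run into twelve 10-s windows,
averages the scans of each window into one spectrum, and discards the last
two windows, keeping 10 analysis spectra ("fragments") per specimen.
Averaging trades time resolution for signal-to-noise; discarding the tail
removes the systematically decaying part rather than modelling it.

**Centroiding.**  A grid point is a peak iff it is a strict local maximum
with intensity at least `noise_k` (default 5) times the median absolute
deviation of the whole fragment spectrum and at least `min_rel_intensity`
(default 0.001) of the base peak.  The vendor's peak-picking algorithm is
unpublished, so these two thresholds are this package's own choices: the MAD
multiplier is the conventional robust noise floor, and the relative floor
mainly protects against pathological flat-plus-spike spectra.  The peak
*m/z* is the intensity-weighted centroid of the three points around the
apex, which is exact for a symmetric peak sampled symmetrically and
first-order accurate otherwise; the apex intensity is reported.

**Alignment.**  Only a tolerance (0.5 Da) is specified for matching peaks
across spectra, not an algorithm.  We pool all peaks of all fragments, sort
by *m/z*, and cut the sorted pool wherever the gap between consecutive
values exceeds the tolerance.  This is exactly single-linkage clustering
with cut height 0.5 Da (the test suite asserts equivalence against
`hclust(..., "single")` on random instances), and it is deterministic and
independent of sample order — properties a greedy reference-spectrum matcher
would not have.  The consequence, documented rather than hidden, is that a
*chain* of peaks 0.4 Da apart lands in one bin wider than the tolerance;
the gap rule guarantees only that consecutive member gaps never exceed it.
An optional `max_bin_width_da` splits chained bins at their largest internal
gap, off by default to preserve pure single-linkage semantics.  Within a
bin, multiple peaks from one fragment are summed, not max-pooled, so the
total ion current is conserved through alignment.

**TIC normalization** divides each fragment row by its own sum, after
alignment (matching the stated order of operations) and on the picked peaks
rather than the raw continuum — whether the original software normalizes on
the continuum TIC is unknowable, and normalizing the picked peaks keeps the
feature matrix self-contained.  The operation is idempotent and invariant to
per-row scaling, and rows are verified to sum to 1 within 1e-9 whenever a
matrix claims to be normalized.

## The synthetic cohort generator

No raw spectra are publicly deposited, so the generator is a first-class
module that reproduces the *statistical structure* the analysis assumes, at
the study's geometry: 117 HCC patients (105 paired with non-tumour tissue)
and 50 MFCCC patients (46 paired) — 318 specimens, 3,180 analysis spectra.

The expected intensity of library peak $j$ at scan time $t$ in tissue class
$c$ is

$$\mu_{j}(t) = \exp\big(\beta_j + \gamma_{cj} + u\big)\, d(t), \qquad
d(t) = \begin{cases}1 & t < t_0\\ e^{-(t-t_0)/\tau} & t \ge t_0\end{cases}$$

with $\beta_j$ the base log-intensity (uniform on $\log 200$–$\log 5000$
counts), $\gamma_{cj}$ the class effect, and $u \sim N(0, \sigma_u^2)$ a
patient random effect shared between a patient's tumour and matched
non-tumour sample.  Each scan's realized peak intensity is
$\mu_j(t)\,e_{js}$ with $e_{js}$ log-normal (sd `scan_sd`), peaks are
Gaussian in *m/z* (sd `peak_width_sigma` = 0.2 Da) rendered on a 0.1 Da
grid, and an additive Gaussian noise floor (sd 2 counts, truncated at 0)
covers the grid.  Choices worth recording:

* **Multiplicative log-normal noise** (patient and scan) because MS
  intensities are positive and heteroscedastic; no noise model is published
  for this instrument.
* **Per-peak-per-scan** draws for $e_{js}$: a single factor shared by all
  peaks of a scan would cancel exactly under TIC normalization and make
  `scan_sd` a silent no-op downstream.  For the same reason the scalar
  patient effect $u$ *is* removed by TIC normalization — it models
  specimen-size/ionization-efficiency differences, which TIC normalization
  exists to remove; class information enters only through $\gamma_{cj}$.
* **Decay as smooth exponential** starting at $t_0 = 100$ s with
  $\tau = 20$ s: the source analysis states only that the last two windows
  are "less consistent"; an onset inside the last two windows with a decay
  visible above noise is the simplest mechanism producing exactly that
  inconsistency, and the generator invariant (trailing windows have lower
  TIC whenever $t_0 \le 100$ s) is tested.
* **Class effects**: each discriminative peak carries a single effect of
  magnitude `delta` (random sign) on the tumour class of its contrast; the
  three contrasts' peak sets are disjoint.  Default `delta` = 2 log-units
  represents the strong separation the real study reports (94–99%
  accuracy); `delta = 0` gives an exact null.  Peak positions are drawn at
  ≥ 2 Da spacing so alignment bins are unambiguous in expectation — noise
  maxima on peak shoulders still create sparse extra bins, as in real data.
* **Geometry**: 1 scan/s (120 scans), 0.1 Da grid (19,901 points).  The
  grid is fine enough that the 0.5 Da alignment tolerance is meaningful and
  coarse enough for desk-scale runtimes.

What passing tests on this generator do **not** show: robustness to mass
drift between runs, isotope envelopes and adducts, retention-free matrix
effects, inter-centre instrument variation, or non-scalar patient effects —
real spectra differ in all of these.  The generator validates the
*pipeline's statistics* (leakage-free CV, calibration, vote arithmetic),
not clinical performance.

## PLS-DA

Partial least squares discriminant analysis is implemented as NIPALS PLS2 on
the column-mean-centred feature matrix against the centred one-hot class
matrix, deflating X and Y after each component.  NIPALS was chosen over
SIMPLS/kernel variants because every quantity it produces is directly
checkable against a brute-force oracle: the first weight vector equals the
dominant left singular vector of $X_c^\top Y_c$, which the tests assert to
$|\cos| > 1 - 10^{-6}$.  Determinism comes from initializing the inner loop
at the Y column of maximal variance; convergence is declared at a relative
score change below $10^{-10}$ (at most 500 iterations, then an error with
diagnostics).  Mean-centring only, no unit-variance scaling, by default:
TIC-normalized intensities share a scale, and scaling up rare noise bins
would be harmful (configurable via `scale = TRUE`).  Two components are
fitted by default — what a score plot displays.  Explained X-variance per
component is reported; its monotone decay is an empirical regularity on
this kind of data (asserted in the tests for the synthetic cohorts), not a
theorem for PLS, whose components maximize covariance with Y rather than
X-variance.  PLS-DA is deliberately diagnostic only; classification uses
SVM/RF.

## Classification and evaluation

**Grouped folds.**  Fold assignment is at patient level: patients are
shuffled within strata (cohort × sample profile) by a seeded RNG and dealt
round-robin, so every fragment of every sample of a patient shares a fold,
fold sizes differ by at most one patient per stratum, and each fold's class
mix approximates the global patient-level mix.  Stratification is this
package's choice (grouping alone is stated in the source analysis); it
prevents accidental single-class test folds at small K.

**Classifiers.**  The original software's hyperparameters are unpublished,
so documented, config-overridable defaults are used: an RBF-kernel SVM with
cost 1 and $\gamma = 1/(p \cdot \mathrm{var}(X_{std}))$ on per-feature
standardized inputs (standardization learned on the training fold only;
zero-variance features pass through), and a random forest with 500 trees
and $\lfloor\sqrt{p}\rfloor$ feature subsampling, seeded and
single-threaded so repeated runs are byte-identical.  Consequently the
package's validation rests on arithmetic reconciliation of the published
counts and on synthetic recovery, not on matching real-data accuracies.

**Error taxonomy.**  Concordant = exact match; false positive = true
non-tumour predicted as either tumour class; false negative = true tumour
predicted non-tumour; misclassified = HCC predicted MFCCC or vice versa
(possible only in the three-class task; structurally zero in binary tasks).
Sensitivity and specificity are the concordant fractions of tumour and
non-tumour units.  Note the published description of the HCC-vs-non-tumour
SVM result labels its two error counts inconsistently with its own printed
sensitivity and specificity; this package always computes metrics from its
own confusion counts, under the conventional definitions above.

**Majority vote.**  A specimen is concordant iff at least
$\lceil n/2\rceil$ of its $n$ predicted fragments are correct (5 of 10 at
the defaults).  The specimen's predicted label is the modal fragment
prediction; a modal tie is flagged `indeterminate`.  In the sample-level
confusion, concordance follows the vote rule, and non-concordant specimens
are categorized by their modal label; the rare specimen whose modal label
is tied or even correct despite a failed vote is counted conservatively as
false negative (true tumour) or false positive (true non-tumour), keeping
the four counts an exact partition of the total.  Empirically (and by the
binomial tail $P(X \ge 5)$, $X \sim \mathrm{Bin}(10, 1-p)$, verified
Monte-Carlo in the tests), the vote improves on fragment accuracy whenever
fragment accuracy exceeds one half and errors are exchangeable within
specimen.

## Calibration check

The daily instrument check matches each reference-standard ion (expected
*m/z* and intensity relative to the base peak) to the nearest observed
peak, ties toward lower *m/z*.  Pass requires every ion matched within
`mass_tol_da` and every intensity ratio within `ratio_tol_fraction`
(relative).  The monitored-ion table ships as data — a synthetic example
file, as the real monitored ions of the polypropylene-glycol standard are
not published — and the vendor's pass thresholds being likewise
unpublished, defaults of 0.5 Da and 30% are package choices.

## Problem sizes and numerical conventions

The test suite exercises reduced cohorts (3–8 patients per arm, 0.5 Da
simulation grid) for unit and property tests, chosen as the smallest sizes
at which every pipeline property is non-trivial; the acceptance checks run
the full 318-specimen geometry on the 0.1 Da default grid, plus a 30-patient
balanced null arm.  The null-calibration interval is the 99% binomial CI of
0.5 computed at the *specimen* count, not the fragment count: fragments of
one specimen are correlated by construction, so the specimen is the
exchangeable unit.  All m/z values are 64-bit reals in Da; text round-trips
use 15 significant digits (lossless within 1e-9); every stochastic step
(library, cohort, folds, forests) derives from one integer seed, and
per-sample/per-fold streams are derived as `(seed * 10007 + 131 i) mod
(2^31 - 19)` so they stay in 32-bit range.

## Known limitations

* The scan-table format is this package's own (the vendor export schema is
  proprietary); mzML import is not implemented — converters to the
  documented text format are straightforward.
* Negative-ion mode has no counterpart in the simulator or pipeline
  configuration; the source analysis found it uninformative and the
  simulator has no polarity concept.
* No retention-time warping, isotope deconvolution, lock-mass
  recalibration, VIP-based biomarker ranking or peak identification — out
  of scope by design.
* Published specimen-level denominators for the tumour-type (HCC vs MFCCC)
  comparison cannot be reconstructed from the cohort sizes; those
  quantities are not reconciled, only the three tasks' fragment counts and
  the binary-task rates.
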