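---
title: "Methods: pulse wave velocity estimation on a vascular phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse wave velocity estimation on a vascular phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvlab)
```

## The problem

Pulse wave velocity is the standard functional surrogate for arterial
stiffness, and the Moens–Korteweg relation

$$\mathrm{PWV} = \frac{D}{\mathrm{PTT}} = \sqrt{\frac{E\,W}{\rho\,d}}$$

ties it to the mechanics of a thin-walled elastic tube: Young's modulus $E$
of the wall, wall thickness $W$, fluid density $\rho$, and inner diameter
$d$. On a physical phantom — silicone artery segments of controlled Shore A
hardness and wall thickness, driven by a pulsatile pump — all of these are
known or measurable, so the full chain from waveform morphology to hardness
to elasticity to PWV can be validated against a two-site transit-time
reference measured on the same rig.

`pwvlab` implements that chain and, because the physical rig is not
required, ships a synthetic-data generator that emulates the study design
closely enough for every stage to be tested against known ground truth.

The Moens–Korteweg model assumes an ideal elastic, homogeneous, isotropic,
thin-walled tube and incompressible fluid. Viscoelasticity of real arterial
tissue, non-Newtonian blood behaviour, and wave reflections are outside its
scope and outside the scope of this package.

## The synthetic generator

### What it emulates

One *trial* is a configuration of stroke volume (10 or 20 mL), nominal
heart rate (30/60/80 bpm), wall thickness (1/1.5/2 mm) and Shore A hardness
(10–50), giving the 90-trial factorial grid of the study design
(`make_config_grid()`); the three-hardness subset gives 54. Each trial
produces a four-channel record (`p1`, `c1`, `c2`, `p2`): upstream pressure,
two capacitive channels at one-sixth and five-sixths of the sensor
separation, and downstream pressure at 0.30 m.

The beat shape is a sum of Gaussian lobes on a constant 30-unit baseline
(the maintained line pressure): a systolic lobe, a dicrotic lobe, and a
shallow onset dip. The dip deserves a note: real pulse feet are *sharp* —
a near-flat diastolic run-off broken by a rapid upstroke — whereas the
inter-lobe valley of a pure two-Gaussian model is flat to within machine
precision, which would make the foot location ill-conditioned and
un-testable. The dip pins the foot with finite curvature while keeping the
template band-limited (its width scales with the systolic lobe so that the
adaptive low-pass filter does not displace it). Landmark truth (foot,
rising steep, peak, falling steep, notch) is computed from the continuous
template by root finding on its closed-form derivative, not read off the
sampled grid.

Morphology follows the qualitative trends reported for stiffer vessels:

* pulse pressure increases with hardness and stroke volume
  (`pp = 8 + 0.6*SV + 0.25*ShA`, in mmHg-like units chosen so the grid
  spans roughly 15–35);
* the systole fraction of the cycle increases with hardness
  (`zeta = 0.22 + 0.003*ShA`, spanning about 0.25–0.37 and constrained to
  (0.15, 0.6));
* the dicrotic lobe shrinks with hardness (`0.18 - 0.002*ShA` of the
  systolic amplitude), so the softest segments show a clear notch and the
  stiffest a barely-there shoulder.

These coefficients are the package's own calibration: no waveform equations
are published for the rig, so they were chosen once to keep every feature
in a physiologically plausible range and are not tuned further.

Ground truth physics: hardness is converted to elasticity by the Ruess
model (selectable), PWV follows from Moens–Korteweg at the trial's wall
thickness, and the downstream channels are the *clean* upstream signal
delayed by `distance / PWV` via linear interpolation (the delays are
sub-sample at 200 samples/s — the very reason the study design uses a
2000 samples/s mode for the reference measurement) and scaled by an
attenuation factor (0.95). Drift (a 0.05 Hz sinusoid, below the 0.2 Hz
baseline-removal cutoff), white noise (2% of pulse pressure), and small
per-trial jitters on pulse pressure (3% log-normal), systole fraction
(0.005 absolute) and realized pump rate (0.5%) emulate material and
assembly variability. All draws descend from one integer seed through
stable per-trial sub-seeds, so identical settings give bit-identical
datasets.

### What it does not emulate

No fluid–structure interaction, no viscoelastic wall, no Windkessel
dynamics, no wave reflections, no sensor physics. Passing tests on this
generator demonstrate that the *pipeline* is correct — that detection,
features, models and statistics recover what was put in — not that the
pipeline would achieve any particular accuracy on data from the physical
rig, which carries noise and morphology this generator does not model.

## Signal conditioning

Baseline removal is a 4th-order Butterworth high-pass at 0.2 Hz applied
forward–backward (`signal::filtfilt`), which removes the constant line
pressure and sub-cutoff drift with zero group delay. The filter family and
order are the package's choice (flat passband; only "zero-phase" and the
cutoffs are fixed by the study design). Two numerical details matter at
such a low relative cutoff: the signal is demeaned before filtering,
because the near-unit-circle poles amplify roundoff in proportion to the
absolute signal level; and both filters use odd-reflection end padding
sized to three filter time constants, so edge transients decay inside the
pad rather than inside the record.

The low-pass cutoff is selected from the *nominal* pump rate by a
nearest-of-{30, 60, 80} lookup mapping to {3, 6, 8} Hz — the fixed
three-cutoff scheme of the study design — which retains at least four
harmonics of the fundamental in every case. Rates above 120 bpm would push
the fourth harmonic past 8 Hz and are rejected. Welch spectral estimation
(8 s Hann segments, 50% overlap — parameters of the package's choosing)
provides an independent fundamental-frequency estimate with a
low-confidence flag when no peak stands 3x above the in-band median power.

Amplitude normalization maps each record to [0, 1] and keeps the affine
coefficients as attributes, because pulse pressure must be measured in
pre-normalization units.

## Fiducial detection

Beats are segmented around systolic peaks (local maxima with a refractory
period of 0.6 nominal cycles — the peak-search parameter is not fixed by
the study design and is documented here), with windows spanning
midpoint-to-midpoint between adjacent peaks. Windows clipped at the record
ends are flagged invalid: they are not true midpoint-to-midpoint beats and
sit in the residual filter-transient region.

Within a beat, with $d_1, d_2, d_3$ the central-difference derivatives:

* **foot** — last negative-to-positive zero crossing of $d_1$ before the
  peak ("the last minimum before the systolic peak"), taking the sample
  whose $d_1$ is nearer zero; argmin fallback when filtering leaves no sign
  change;
* **rising steep** — argmax of $d_1$ between foot and peak;
* **falling steep** — first local minimum of $d_1$ after the rising steep;
* **dicrotic notch** — first sign change of $d_3$ strictly after the peak,
  absent when none occurs in the window.

Beats violating the ordering foot < rising < peak < falling are dropped,
not repaired. The notch is detected and counted but never propagated into
features — on phantom-like waveforms its detection is unreliable, and
downstream models must not inherit that unreliability.

## Features

Per beat: crest time (foot to peak; the "first zero-crossing of the pulse
derivative" after onset *is* the peak, which makes crest ≤ systole
structurally true), systole time (foot to falling steep), pulse pressure
(foot-to-peak amplitude, pre-normalization), pulse-to-pulse interval
(foot to next foot). Trials aggregate by the **median** across beats — the
robust choice, and the one fixed for transit times; whether the original
analysis used mean or median for features is unstated, so the median is
applied uniformly. Time features are normalized to percent of the median
cycle so trials at different pump rates are comparable. The engineered set
is frozen at nine features: `rr = 60/HR`, `systole_over_rr`,
`crest_over_rr`, `sv_over_pp`, `pp_over_sv`, `pp_over_w`, `w_times_pp`,
`log1p_pp`, `log1p_sv`.

## Hardness models

**OLS.** `fit_regression()` regresses Shore A hardness on ST, PP, SV, HR
and W after a single-pass Cook's-distance screen at the conventional $4/n$
threshold (the threshold is the package's choice; the screened count is
data-dependent). The fitting is unit-agnostic in ST — the reported
equation's ST coefficient is plausible under either seconds or fraction-of-
cycle units, and the recovery tests pin only the printed coefficients.
Exact fits short-circuit the screen, since influence is numerically
undefined when $s^2 \approx 0$.

**ANFIS.** A first-order Sugeno system: six inputs, each min–max scaled to
[0, 1] and covered by two Gaussian membership functions (centers at the
extremes, width `range/(2(m-1))`), full grid rule base ($2^6 = 64$ rules),
affine rule consequents, weighted-average defuzzification. That is 448
linear parameters and 24 premise parameters. A published architecture
summary for this configuration reports "36 nonlinear" parameters alongside
the same 64 rules and 448 linear parameters; the counts are mutually
inconsistent (24 is what $2 \times 6 \times 2$ Gaussians give), so this
package matches the rule and linear-parameter counts and documents the
discrepancy here.

Training is the classic hybrid scheme, 30 epochs by default: each epoch
solves all consequents jointly by ridge-regularized least squares
($\lambda = 10^{-8}$; the dual form is used when the design has fewer rows
than parameters, as with 64 rules on ~68 training rows) and then takes one
batch gradient step on the centers and widths, normalized to unit gradient
length with Jang-style step-size adaptation (x1.1 after an improving
epoch, x0.5 after a worsening one, initial 0.01). Consequent updates are
accepted only when they do not increase training SSE; widths are floored
at $10^{-4}$. A stratified 75/25 holdout (seed 42 by default; the split
ratio is part of the study design, stratification and seed are not) tracks
generalization per epoch. With one membership function per input the model
collapses to a single rule and the LSE step reproduces OLS — a useful
structural cross-check that the tests exercise.

Because 64 rules against ~68 training rows is underdetermined, the trained
system interpolates its training data; on the synthetic grid the holdout
$R^2$ is the honest generalization number (about 0.93 under the default
conditions), not the near-zero training RMSE.

## Benchmarks

`run_benchmark()` evaluates 14 model families under stratified 5-fold
cross-validation in two scenarios (five-class FULL, three-class LOW),
standardizing features with training-fold statistics, pooling out-of-fold
predictions, and snapping regression outputs to the nearest class on the
scenario grid (midpoint ties to the higher class, out-of-range clamped).
Metrics are macro-averaged one-vs-rest F1, sensitivity and specificity
(zero-division contributes 0), plus MAE and RMSE on the numeric class
labels. Established implementations back the standard learners (`nnet`,
`e1071`, `class`, `randomForest`, `xgboost`, `glmnet`); the three neural
baselines (softmax MLP, CORAL ordinal head with a shared output weight
vector and independent ordered biases, MC-dropout with 100 stochastic
passes) run on a small dense-network engine written for this package — two
hidden ReLU layers (32, 16), Adam, inner stratified 80/20 early-stopping
split with patience 20 — since no installed R package provides dropout
MLPs.

## Elasticity, PWV and validation statistics

Five conversions map Shore A to MPa; all are exponential-family fits for
silicone except Gent, whose published rendering is typographically garbled
and is reconstructed here as the standard Gent relation
$E = 0.0981\,(56 + 7.62336 S) / (0.137505\,(254 - 2.54 S))$ — the
reconstruction reproduces all five published Gent table cells at two
decimals. $\rho = 1000$ kg/m³ and $d = 10$ mm are not printed anywhere in
the source tables; they were inferred by inverting the Moens–Korteweg
relation against the published PWV grid (e.g. DMA at ShA 50, W 2 mm gives
$d = EW/(\rho\,\mathrm{PWV}^2) = 0.0100$ m) and are frozen as overridable
defaults. **Unrounded** elasticity feeds the PWV computation: rounding $E$
to two decimals first changes PWV cells in the second decimal (35.47 vs
35.46 at DMA/50/2 mm).

The reference transit time pairs feet between the two pressure channels by
nearest-time matching within half a cycle (the pairing rule is the
package's choice) and takes the median across beats; reference PWV is
distance over transit time. Paired errors (estimate − reference) pass
through a Shapiro–Wilk gate at $\alpha = 0.05$: normality not rejected →
two-sided one-sample t-test against zero; rejected → two-sided Wilcoxon
signed-rank (zeros dropped, normal approximation above n = 25). All-zero
differences short-circuit to a degenerate flag. Error statistics are
pooled across all setups per conversion model; finer pooling (per wall
thickness) is not fully specified in the source analysis, so pooling-all
is the documented choice.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 20 s records at
200 samples/s for feature work and 12–15 s at 2000 samples/s for the
reference transit-time mode — enough for 6–26 analyzable beats per trial
at 30–80 bpm, which is where the median aggregation stabilizes; these
sizes are the package's own choice of a compact but statistically
meaningful experiment. Degenerate inputs are rejected loudly rather than
repaired: constant signals cannot be normalized, constant inputs cannot
seed membership functions, cycles with fewer than 20 samples cannot carry
five landmarks, transit times of at least one cycle are unphysical.

## Known limitations

* The generator's beat is a three-lobe Gaussian composite: it carries all
  five landmarks and the documented morphology trends, but not the full
  shape vocabulary of pressure waveforms (no reflected-wave shoulder, no
  late-systolic augmentation), so augmentation-index-style features are
  out of scope by construction.
* Hardness enters the synthetic morphology affinely, which makes the
  synthetic hardness-estimation task easier than the physical one; the
  benchmark's absolute scores on synthetic data say nothing about rig
  data, only the machinery's correctness does.
* The ANFIS rule base grows exponentially in the number of membership
  functions per input; the grid-partition default is only practical at
  2 MFs for 6 inputs.
* The deposited-dataset loader is a contract (`read_record_csv` dialect),
  not a parser for the archive's internal format.
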