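---
title: "Detecting seated-reaching compensation from pressure distributions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seated-reaching compensation from pressure distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seatcomp)
```

## The detection problem

During seated reaching, stroke survivors often recruit trunk or scapular
degrees of freedom to substitute for the impaired arm: leaning the trunk
forward (TLF), rotating it axially (TR), or elevating the shoulder girdle
(SE). Each of these moves mass relative to the seat, so each leaves a
signature in the time course of the seat-pressure distribution. `seatcomp`
classifies single reaching repetitions, recorded as sequences of 32 × 32
sensor frames at 50 Hz, into NC (noncompensated), TLF, TR or SE.

The method rests on two assumptions worth stating plainly:

1. **Compensation redistributes seat load.** Trunk lean-forward moves the
   centre of pressure (COP) toward the front of the seat; trunk rotation
   and shoulder-girdle elevation shift load laterally and asymmetrically
   between the two ischial tuberosities. Pure arm movement without trunk
   involvement perturbs the seat distribution only mildly.
2. **Volatility, not position, is the signature.** Subjects differ in
   where they sit and how much they weigh, so absolute COP position is a
   poor feature. The standard deviation of the COP and pressure-ratio
   series over a repetition captures how much the posture moved,
   independent of where it started.

## Features

For sensor `i` at lateral coordinate `x_i` (column, left = 1) and
longitudinal coordinate `y_i` (row, front = 1), with value `p_i(t)`:

* `SSV(t) = Σ_i p_i(t)` and `ASV = Σ_t SSV(t) / T` — the average total
  load (device units), reflecting movement amplitude and sitter weight;
* `LatCOP(t) = Σ_i x_i p_i(t) / SSV(t)` and the analogous `LonCOP(t)` —
  pressure-weighted mean coordinates (sensor units);
* `LRratio(t)` — left-half over right-half summed pressure;
  `FBratio(t)` — front-half over back-half (dimensionless).

One trial yields the five-vector (ASV, SD_LatCOP, SD_LonCOP, SD_LRratio,
SD_FBratio), the SDs taken over frames.

Numerical conventions, chosen once and documented because degenerate
inputs exist:

* **Axis convention for the ratios.** The `axis_mode = "semantic"` default
  splits the left/right ratio along the lateral axis (columns) and the
  front/back ratio along the longitudinal axis (rows), so each ratio
  matches its name and the posture phenomenology (rotation produces
  lateral asymmetry, lean-forward a front/back shift). A `"literal"` mode
  that swaps the two index sets is retained for fidelity with sources
  that index the halves by the other coordinate; on the generator's data
  the semantic split is the informative one.
* **Zero-pressure frames.** A frame with `SSV(t) = 0` has no defined COP,
  and a frame whose denominator half sums to zero has no defined ratio.
  Such frames are flagged invalid and excluded from the four SDs but still
  count in `T` for the ASV, whose definition divides by total time. A
  trial needs at least two valid frames; otherwise feature extraction
  errors, naming the trial.
* **Sample SD** (`n − 1` denominator) throughout. The choice is
  immaterial to any relative comparison but is fixed for reproducibility.
* **Offset correction** subtracts a per-sensor bias matrix and clips
  negative differences to zero, since pressure cannot be negative.

## Classifiers and evaluation protocol

Features are standardized to zero mean and unit variance with moments
learned from the training rows of each fold only; the identical transform
is applied to test rows. Refitting the standardizer on test subjects would
leak their scale into the model and flatter the generalisation estimate.

* **k-NN**: Euclidean metric on the standardized five-vector. k is chosen
  from {1, 3, …, 15} by an inner, subject-grouped validation on the
  training subjects, maximising macro F1; ties go to the smallest k.
  Prediction ties are resolved deterministically (the vote-tied class
  containing the nearest neighbour wins; equal distances are ordered by
  training-row index) so that results are bit-reproducible.
* **Linear SVM**: soft margin, default cost `C = 1`, one-vs-rest for the
  four-class task (one-vs-one available). The quadratic program is solved
  by libsvm via e1071 with termination tolerance 1e-6; each machine's
  hyperplane is stored explicitly as `(w, b)`, and on separable data at
  large cost the margin constraints `y_i (w'x_i + b) ≥ 1` hold to that
  tolerance. A linear kernel is the appropriate capacity for five
  features and a few hundred training rows.
* **Cross-validation** is subject-grouped: the 8 subjects are partitioned
  into 4 folds of 2, each fold's 6 remaining subjects train the model, and
  every subject is tested exactly once. Grouping by subject is essential:
  repetitions by the same person are highly correlated, and trial-level
  folds would overstate accuracy. Metrics are reported per fold and
  pooled over folds (micro aggregation of the confusion matrices); both
  the pooled macro F1 and the mean of per-fold macro F1 are returned
  because the aggregation choice is a genuine reporting ambiguity.
* **Metrics**: per-class precision, recall and F1, macro (unweighted)
  averages, accuracy. Undefined 0/0 cells are reported as 0 with a
  warning so that reports stay total. Displays round half-up to 3
  decimals; computations keep full precision.
* The binary detection task maps {TLF, TR, SE} to a single positive class
  `C` and is evaluated per reaching task, with compensation as the
  positive class (the NC-positive F1 is also reported, since either
  convention is defensible).

## The sEMG verification chain

Nine trunk muscles (LRA, RRA, LOEA, ROEA, LTES, RTES, LLES, RLES, DT) at
2 kHz. Per channel, in order: mean subtraction (baseline correction),
zero-phase 4th-order Butterworth band-pass 20–200 Hz, 4th-order
Butterworth band-stop 48–52 Hz (the 50 Hz power frequency), full-wave
rectification, and amplitude normalization. Design notes:

* **Zero-phase filtering** (forward–backward) is used so that no phase
  distortion enters the amplitude analysis; the effective order of each
  stage is then 8. Filters are applied as cascades of second-order
  sections with odd-reflection edge padding sized to the band's ring-down
  time: the order-8 narrow-band notch is numerically ill-conditioned in
  direct transfer-function form, and unpadded filtering leaves edge
  transients that dominate the residual of a notched tone.
* **Normalization reference.** No maximal-voluntary-contraction protocol
  is assumed, so the default reference is the channel's own trial maximum
  (output in [0, 1]). For comparisons of amplitude across trials or body
  sides this reference must be side-invariant; the built-in sEMG study
  summaries therefore run the chain with `normalize = "none"`.
* **RMS** is taken over the whole motion segment, one value per trial and
  muscle; Ave-RMS averages RMS across subjects per muscle × movement ×
  side cell, with SD (0 by convention for a single subject) and explicit
  flags for empty cells.
* The paired t-test of affected- vs healthy-side Ave-RMS can pool either
  subject × channel cells or per-subject means across the targeted
  channels; both poolings are a single `paired_ttest()` call on the
  corresponding table, and the tests use per-subject means of the
  targeted muscles.

## What the synthetic generator emulates

No clinical recordings are distributed, so the package ships a generator
whose defaults state the study conditions: 8 subjects × 2 sides × 3
reaching tasks (back-and-forth, side-to-side, up-and-down) × 30
repetitions = 1440 trials, 2 s per trial at 50 Hz. Healthy-side trials
are labeled NC. Affected-side trials carry the dominant compensation of
their task — back-and-forth → TLF, side-to-side → TR, up-and-down → SE.
That mapping is a design choice (forward reaching most naturally elicits
trunk lean, lateral reaching trunk rotation, upward reaching shoulder
elevation); a `label_mixture` option assigns patterns at random instead,
for robustness experiments.

The seat model is parametric and deliberately simple: two 2-D Gaussian
bumps at the ischial tuberosities (rows 20, columns 12 and 21, amplitude
60, spread 3 sensors) plus a lower anterior thigh band (amplitude 18).
A reach envelope `e(t) = sin²(πt/T)` drives all movement. Every trial of
a task carries that task's baseline seat displacement (0.8 sensors, or an
8 % amplitude modulation for up-and-down); compensation adds, on the
affected side only:

* **TLF** — a 4-row forward COP shift;
* **TR** — a 3-column lateral shift toward the reaching arm plus a ±25 %
  loading asymmetry toward the arm-side ischium;
* **SE** — a 1-column ipsilateral shift plus a ±30 % ipsilateral loading
  asymmetry (the pelvic hike under shoulder elevation loads the
  ipsilateral ischium; with the opposite polarity the asymmetry's COP
  displacement would cancel the lateral shift and erase the signature,
  which is why the polarity is fixed this way).

Between-subject variability randomises bump centres (SD 0.8 sensors),
overall amplitude (log-SD 0.12) and the affected body side; within-trial
variability adds smooth random sway (0.25 sensors), a per-trial amplitude
jitter (log-SD 0.08), 6 % multiplicative and 1.5-unit additive sensor
noise. Effect sizes and noise were set once so that the default dataset
is separable but not trivially so — cross-validated F1 in the 0.95–1
range, the regime the method is claimed to operate in. The random draws
per trial are identical for every label, so setting all effect sizes to
zero makes a compensated trial bit-identical to an NC trial at the same
seed — the null case used to verify that the pipeline scores at chance
when there is nothing to detect.

The companion sEMG generator produces 20–200 Hz band-limited noise under
the same reach envelope; on the affected side the channels of the muscle
group each pattern recruits (TLF → abdominals and thoracic erector
spinae; TR → lumbar erector spinae; SE → descending trapezius) are scaled
by 1.5.

What the generator does **not** emulate: biomechanically accurate
body–seat contact, anthropometric diversity beyond random offsets,
sensor-array nonlinearity or hysteresis, compound compensation patterns,
or the variability of genuinely impaired movement. Passing tests on this
data therefore validate the pipeline's correctness and its behaviour
under the stated statistical structure — not clinical performance. The
published clinical F1 values can be compared in regime (above 0.95) but
not reproduced, because the underlying recordings are unavailable.

## Problem sizes used in the test suite

Tests verify properties at the smallest size that exercises them: feature
oracles run on 4–8-sensor grids against explicit double loops; the
chance-level and monotonicity properties use 4-subject designs with 6–8
repetitions and 1 s trials over 3 seeds (three effect levels, tolerance
one SD); the sEMG direction check uses 20 seeded replicates of a
3-subject study plus one 8-subject study for the paired test; the
full-design evaluation runs once at the complete 1440-trial default. These
sizes are the package's choices for a suite that a developer runs on
every change.

## Known limitations

* Detection is per repetition on pre-segmented trials; segmenting a
  continuous recording is out of scope.
* One dominant pattern per trial: compound compensation maps to whichever
  single pattern dominates the seat signature.
* The method grades presence, not severity; the features carry no
  calibrated units of compensation magnitude.
* The ratio features are undefined when a grid half carries no load;
  such frames are excluded rather than imputed, which assumes they are
  rare and uninformative.
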