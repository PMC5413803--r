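---
title: "Quantifying the pronator drift test: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pronator drift test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtkit)
```

## The measurement model

The pronator drift test asks a subject to hold both arms extended,
palms up, eyes closed. Proximal weakness shows as a slow downward
*drift* of the forearm and a *pronation* of the palm, often with a
rapid jitter superimposed. pdtkit instruments the test with one 3-axis
accelerometer per wrist, volar-mounted: Y along the forearm toward the
fingers, X across the wrist toward the thumb (right arm; left-arm
devices are mirrored in X at load time), Z out of the device face.

At the quasi-static postures of this test, the accelerometer measures
mostly the gravity reaction. The package isolates that component with a
zero-phase low-pass filter and converts the unit gravity direction
g = (gx, gy, gz) into

- drift θ = asin(gy) — 0° when the forearm is horizontal, positive when
  the hand falls below the horizontal plane, range [−90°, 90°];
- pronation φ = atan2(gx, gz) — 0° palm-up, positive toward prone,
  range [−180°, 180°].

These formulas are the package's contract for the tilt geometry; their
exact inverse, g = (sin φ cos θ, sin θ, cos φ cos θ), is the forward
model used by the simulator, which is why noise-free signals round-trip
to within 0.01° RMS (well inside the 0.5° the tests require). When the
forearm is exactly vertical (gx = gz = 0) pronation is undefined; the
series holds the last valid value and warns, since that posture lies
outside the test protocol.

### Gravity isolation

Drift and pronation are postural changes well below 1 Hz, so the
gravity estimate uses an order-2 Butterworth low-pass at 1 Hz (default,
configurable) applied forward–backward for zero phase lag. R's
`signal::filtfilt` does not handle edges, so the package pads each axis
with odd reflections (3/cutoff seconds) before filtering and trims
afterwards; a constant input then passes through exactly, and start-up
transients never reach the retained samples. A consequence worth
knowing: tremor-band oscillation (the simulator's default is 3 Hz) is
attenuated by the same filter (|H(3 Hz)| ≈ 0.11 at the default cutoff),
so the OSC features measure the *residual* jitter after gravity
filtering, not the raw tremor amplitude. They remain severity-scaled
and usable, but AVG and MAX carry most of the class signal.

### Sampling

No sampling rate is assumed beyond Nyquist adequacy; the default is
50 Hz. Irregularly spaced input (spacing deviating from the nominal
rate by more than 1%) is resampled by linear interpolation at load
time; shuffled timestamps are rejected, never silently reordered.

## The 12 PDT features

Analysis uses the half-open window [10 s, 20 s) of a 20 s test — the
first half is excluded because of the *initial dip*, a transient
downward excursion caused by device weight and postural settling. The
half-open convention makes sample counts deterministic (exactly
(20 − 10) × rate samples).

Each of the four windowed angle series (drift/pronation × weak/counter
side) yields three statistics:

| statistic | definition | units |
|---|---|---|
| AVG | arithmetic mean | degrees |
| MAX | signed maximum (greatest downward drift / greatest pronation) | degrees |
| OSC | RMS of the linearly detrended series | degrees RMS |

MAX is deliberately *signed*, not an absolute value: an arm that rises
(cerebellar-type updrift) produces a negative drift MAX rather than
masquerading as weakness. OSC is invariant to any affine trend by
construction; a reversal-count variant (direction changes per second)
is available behind `osc = "reversals"` for users who prefer a
zero-crossing notion of jitter. The detrended-RMS closed form
OSC = A/√2 for a zero-mean sine holds to better than 1% once the
window contains many cycles; over very few cycles the detrending line
absorbs part of the sine, which is the expected behaviour of the
definition, not an artefact.

Controls have no weak side; their non-dominant arm is recorded as the
weak-equivalent side by the cohort generator, and that labelling
travels with the roster metadata. Subjects graded MRC 0–3 are excluded
before any model sees the data: the test presumes the subject can hold
the arm against gravity plus the device's weight.

## Classifiers

All three families are fitted on the same labelled dataset (+1 patient,
−1 control) and expose a monotone score for ROC use; decision-boundary
ties go to the control class in every family (conservative and
deterministic).

**SVM.** Polynomial kernel K(x, z) = (x·z + 1)^d with d = 2 and C = 1
by default; both are configuration keys, and the defaults reflect that
a curved decision surface is needed in the feature space while the
cohort sizes (tens of subjects) do not support heavy tuning. Features
are standardised (training fold only) because polynomial features mix
degree scales. The score is evaluated directly from the stored support
vectors, so a saved model is a complete JSON document.

**RBF network.** Prototypes are K-means centroids of the standardised
training features; widths follow the within-cluster spread
βᵢ = 1/(2σᵢ²) with σᵢ the RMS member–centroid distance floored at 1e−6
(singleton clusters then behave as near-delta neurons, which is what
makes the K = n configuration an exact interpolator). Empty clusters
are re-seeded from the data, deterministically. Read-out weights are
least squares against one-hot targets; the decision is the argmax and
the ROC score the positive-class softmax. Defaults: K = 2 when feature
selection has reduced the space, K = 4 without selection. A
single-class fit is permitted and degenerates to a constant predictor.

**Random forest.** 100 trees, ⌈√m⌉ candidate features per split, Gini
splitting, fixed seed; the score is the positive vote fraction. Forests
are serialised tree-by-tree as node tables, and a reloaded model walks
those tables, reproducing the in-memory votes exactly.

## Wrapper feature selection

Merit of a subset = leave-one-out accuracy of the wrapped classifier on
that subset (the empty subset scores the majority-class proportion).
Best-first search starts from the empty set, keeps an open list ordered
by merit, expands the best node into all single-feature additions and
deletions (bidirectional by default; forward-only is a switch), and
stops after 5 consecutive non-improving expansions. Every evaluated
subset is memoised; merit ties break toward the smaller subset, then
lexicographic index order — so twelve identical copies of one feature
select exactly one. On spaces of up to five features the search
provably (by exhaustive enumeration in the tests) attains the global
optimum across 20 seeded datasets.

Selection placement matters with leave-one-out evaluation:

- `pooled` — selection runs once on all subjects, the chosen subset is
  reused in every fold. This is how small-cohort studies typically
  report; it is optimistically biased because the held-out subject
  influenced the subset.
- `nested` — selection reruns inside every training fold; unbiased and
  roughly n times more expensive.

Both modes are first-class; the package asserts (over 50 small seeded
cohorts) only the *direction* of the bias — pooled ≥ nested on average
— not its size.

## Evaluation

Leave-one-out cross-validation refits the model n times with seeds
derived per fold (`seed + i`), so a rerun reproduces every fold.
Reports carry the confusion counts, sensitivity, specificity, accuracy,
F-measure, the ROC polygon (one vertex per distinct score, which gives
tied scores the conventional half credit) and trapezoidal AUC; the AUC
equals exhaustive concordant-pair counting, which the tests verify on
100 random instances. Group differences use Welch's t test per feature,
uncorrected for multiplicity (12 tests, reported per-feature as is
conventional for descriptive tables; a correction can be applied
downstream). Relative improvements are reported as
100 × (after − before)/before, rounded to two decimals.

## The synthetic cohort generator

Weakness severity s ∈ [0, 1] drives a kinematic model per subject:

θ(t) = dip(t) + s·drift_max·(1 − e^{−t/τ}) + s·osc_amp·sin(2π f t + φ₀) + wobble

with pronation analogous (pron_max, own phase, no dip term — the dip is
a drop of the arm, not a rotation). The dip is a half-sine of depth
10° recovering by 5 s, safely before the default analysis window; the
tests confirm the dip changes windowed features only when the window is
moved to include it. The counter limb mirrors the weak limb's
deterministic trajectory scaled by the coupling, with independent
wobble. Angle trajectories pass through the exact inverse tilt model
plus white sensor noise.

Defaults (all configurable, none fitted to any outcome): drift_max 30°,
pron_max 60°, τ 4 s, osc_amp 5°, osc 3 Hz, coupling 0.3, sensor noise
0.02 g, wobble 0.5°, 50 Hz, 20 s; patients draw s ~ U[0.4, 1],
controls s = 0. MRC grades follow severity (4 above 0.775, 4+ above
0.5, else 5), which under U[0.4, 1] yields grade proportions of the
order seen in small stroke cohorts. All randomness flows from one
cohort seed through per-subject substreams, so cohorts are
byte-reproducible and individual subjects re-simulable.

**What the simulator does not emulate** — and hence what passing tests
do *not* establish about real recordings: controls sit at exactly zero
drift apart from small wobble, so simulated groups separate far more
cleanly than clinical ones (simulated AUCs saturate near 1.0, where a
real 26-subject cohort yields AUCs in the 0.8–0.98 range); the
counter limb of a *control* is quiet, so counter-side averages are
discriminative here although they need not be clinically; there is no
fatigue, no sensor drift or re-strapping variability, no cerebellar or
parietal drift phenotypes, and no gyroscope channel.

## Validation problem sizes

The shipped validation uses: a 5 × 5 grid of (θ, φ) trajectory
amplitudes for the round-trip oracle; 20 seeded datasets (n = 20,
m = 5) for the selection-vs-exhaustive equality; 100 random instances
(n ≤ 12) for the AUC oracle; one 26-subject cohort for the LOOCV
contract; 5 default cohorts for the nested-selection forest AUC
(mean ≥ 0.9) and 20 for the selection-does-not-hurt comparison across
all families; and 50 small cohorts for the pooled-vs-nested bias
direction. These sizes are the package's validation design; all are
driven from fixed seeds.

## Known limitations

- The angle contract assumes a quasi-static arm; ballistic movements
  violate the gravity-isolation premise.
- OSC is measured after the gravity filter and therefore understates
  raw tremor amplitude (see above).
- Pooled-mode metrics on small cohorts inherit selection bias; prefer
  nested mode when the estimate itself is the deliverable.
- The RBFN width heuristic ties all neurons to within-cluster spread;
  strongly anisotropic clusters would call for per-dimension widths,
  which the model does not implement.
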