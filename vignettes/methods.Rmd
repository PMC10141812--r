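---
title: "Detecting deceptive speech from facial landmarks and pulse rate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting deceptive speech from facial landmarks and pulse rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deceptrf)
```

## The problem and the model

In a remote interview, a speaker's nonverbal behavior — blinking, mouth
movement, gaze, head pose — and autonomic signals such as pulse rate shift
measurably around moments of deliberate deception. `deceptrf` implements a
frame-level classification pipeline over two synchronized streams:

* a facial-landmark table, one row per video frame (30 fps by default),
  in the OpenFace 2.0 output dialect: 68 face points P0–P67, a 56-point
  eye model E0–E55, two gaze angles, three head-rotation angles and a
  tracking confidence;
* a 1 Hz pulse-rate CSV from a consumer wearable, aligned to frames by
  step repetition (each 1 Hz value covers its following frames) or,
  optionally, linear interpolation at frame timestamps.

Each frame is mapped to a feature vector, frames are labeled positive if
they fall in a window around the onset of a deceptive utterance, the
labeled table is balanced by undersampling, and a random forest is
evaluated with stratified 10-fold cross-validation; impurity-based
importances rank which channels carried the signal.

### Geometric features

All distances are divided by the nasal-bridge length $L$ and all areas by
$L^2$, which makes them invariant to the subject's distance from the
camera and to translation. $L$ is taken as the distance between the
midpoint of the inner brow ends (P21, P22) and the midpoint of the upper
inner eye corners (P39, P42); the four-point construction this
follows is ambiguous as usually stated, so the alternative convention (mean of
|P21−P39| and |P22−P42|) is available as a configuration option — the two
agree on axis-aligned layouts.

Polygon areas (eyes, mouth rings, inter-brow quadrilateral) use the
shoelace formula over the stored landmark order, closed cyclically.
The inter-brow "rectangle" is traversed in convex order (P21, P22, P42,
P39) to avoid a self-intersecting bow-tie. Brow tilt is the least-squares
slope of y on x — in image coordinates (y grows downward), so the sign is
flipped versus visual intuition; this is documented rather than
corrected. Aspect ratios are designated-landmark-pair extents $L_v/L_h$,
not rotated bounding boxes, so they are *not* rotation-invariant by
design. Eye-model indices (extent pairs 8/14 and 11/17 per eye; iris
points 23/27 and 51/55) are configuration, bound in the same dialect map
as the CSV column names, because the customary eye-figure
numbering belongs to the eye model rather than the 68-point face model.

One caveat surfaced by the invariance tests: the mouth-corner-raise
feature is normalized by an absolute sum of y coordinates (the protocol's
formula), so it is scale-invariant but **not** translation-invariant. It
is excluded from the translation-invariance property; all other features
satisfy both invariances to 1e-9.

### Temporal features

Every facial feature gets a centered rolling **population** variance over
±3 s; the pulse gets ±10 s (pulse changes more slowly). Windows truncate
at session edges; missing values are excluded per window, and a window
with fewer than two present values is missing. The implementation centers
the series and uses cumulative sums, so it is O(n) and numerically stable
under constant shifts (tested to 1e-9).

Blink and mouth-closure counts follow a quartile rule: a frame is
"closed" when the area (eye hexagon, inner mouth ring) is below the first
quartile — linear-interpolation convention, type 7 — of that area over
the **entire session**. This deliberately leaks a global statistic across
the later train/test split, a property of the protocol itself; it is
recorded in the feature-table sidecar. The per-frame count is the number
of below-threshold *episodes* (maximal runs) intersecting the trailing
3 s window — "number of times closed", not closed-frame dwell time. Both
per-eye and merged (mean of the two eye areas) blink counts are emitted,
since the protocol leaves open whether the eyes were merged.

Note an intrinsic property of the quartile rule: by construction 25% of
all frames are below the threshold, so on noisy data the counts include
threshold-crossing episodes unrelated to blinks. See "Known limitations".

### Labeling

A frame at time $t$ is positive iff $t \in [\mathrm{onset}-3\,\mathrm{s},
\mathrm{onset}+5\,\mathrm{s})$ for some deceptive utterance onset (the
moment the subject opens their mouth). The half-open convention makes an
unclipped window exactly $8 \cdot \mathrm{fps}$ frames; edge inclusivity
is otherwise unspecified. Overlapping deceptive windows union;
deceptive speech after +5 s and all truthful speech are negative, and a
positive window takes precedence over an overlapping truthful utterance.

### Preprocessing

Fixed order: drop rows with any missing feature → remove outlier rows →
undersample the majority class to the minority count (seeded, without
replacement). Outlier fences are per-feature over the whole dataset.
Two modes exist: the literal rule (drop outside $[Q_1, Q_3]$), kept for
fidelity experiments but pathological — it removes about half the rows
per feature — and Tukey fences $[Q_1 - 1.5\,\mathrm{IQR}, Q_3 +
1.5\,\mathrm{IQR}]$ (default), which, unlike the literal rule, let
full positive windows survive preprocessing the way the protocol's
reported per-subject dataset sizes require.

Two deliberate narrowings of the fence set, both package design
decisions:

* integer event-count columns are exempt — quartile fences on small
  counts would delete precisely the high-count deception frames the
  counts exist to flag;
* by default the fences apply to the 25 raw static features only.
  Rolling variances are strongly right-skewed, and a union of 1.5-IQR
  fences across ~30 skewed columns removes half the dataset, including
  most deception-window rows (their variance columns are elevated —
  that is the signal). Fences on the raw features still remove
  tracking-glitch frames, which is what outlier removal is for.
  `remove_outliers()` accepts any column subset if the full-table rule
  is wanted.

### Classifier and evaluation

No random-forest implementation is available in the target environment,
so the package ships its own: CART trees, gini impurity, bootstrap
resampling, `mtry = floor(sqrt(p))` features per node, 100 trees,
unlimited depth, majority vote; importances are normalized total
impurity decreases, averaged over fold models for cross-validation. All
forest randomness flows through one `std::mt19937_64` seed, so fits are
reproducible across platforms and leave R's RNG untouched.

Cross-validation is stratified, shuffled and **frame-wise** by default,
which is faithful to the protocol's evaluation but optimistic: adjacent
frames are nearly identical (and rolling windows overlap), so a test
frame's neighbors sit in the training set with the same label. The
package therefore also provides grouped folds over contiguous time
segments. Segments default to 30 s — longer than the widest rolling
footprint (±10 s), so interior test frames share no window content with
training frames.

Metrics come from the pooled (summed) fold confusion matrix, which is
what puts the reported counts on the scale of the full dataset; ratios
with zero denominators are reported missing, never zero; 2-dp rounded
views accompany raw values.

## The synthetic world

No human-subject recordings ship with this package (none are publicly
available for this task), so it
generates complete sessions — landmark CSV, pulse CSV, annotation JSON —
from a neutral face template, with ground truth for every injected
event. Defaults state the emulated world and are not tuned per test:

| parameter | default | rationale |
|---|---|---|
| duration, fps | 600 s, 30 fps | a typical webcam recording rate; a session long enough for ~30 utterances |
| utterances | 30, half deceptive, 5–15 s | free-speech description task |
| blink rate | 15 blinks/min, ×3 in deception windows | normal adult blink rate; marked arousal effect |
| mouth | inner-ring opening ×6 while speaking; ×1.3 area shift in windows | speech opens the mouth; deceptive speech slightly wider |
| gaze/head | AR(1) wander, sd 0.08/0.03 rad; sustained window offsets sd 0.1 rad | people look around at this amplitude; "looked up while thinking" |
| pulse | 70 bpm, AR(1) innovations sd 1.5 bpm with slow log-normal drift; variance ×4 in windows | nonstationary heart-rate variability; stress effect |
| jitter | common-mode AR(1) translation sd 1 px + per-landmark residual sd 0.25 px (AR 0.85) | head micro-motion dominates; trackers smooth residuals temporally |
| lid aperture | slow drift, sd 0.18, ~11 s correlation | squinting/lid droop; gives the eye area a realistic lower tail |
| missing pulse | 1 per 1000 samples | the reported missing-value rate |

What the generator does *not* emulate: facial expressions as such
(smiles, brow raises correlated across landmarks), appearance or
illumination effects on tracking quality, subject-to-subject anatomy
differences, pulse-landmark coupling. A green test therefore establishes
that the pipeline recovers the *kinds* of effects it injects at realistic
amplitudes — not that any particular per-subject accuracy would
reproduce on human data.

### The null world and evaluation leakage

With every effect switched off (`null_synth_config()`) positive and
negative frames are distributionally identical, so any faithful
evaluation must return chance accuracy. Two subtleties:

1. Utterance-locked mouth opening is also suppressed in the null world.
   Labels are onset-locked, and undersampling keeps all positives while
   thinning negatives, so "looks like an utterance onset" alone becomes
   predictive of the label through the class prior — a property of the
   labeling-plus-undersampling design, not of deception. Distributional
   identity requires a stationary null.
2. The chance-level check uses grouped folds. Frame-wise folds on this
   generator reach ~0.99 accuracy on *label-independent* features purely
   by temporal adjacency — a vivid measure of how optimistic
   frame-shuffled cross-validation is on video data. The frame-wise mode
   remains the default because it matches the protocol; the
   vignette flags it, and grouped mode is one flag away.

### What the recovery test can and cannot show

When only the pulse-variance and blink-rate effects are injected, the
pulse-variance column reliably tops the importance ranking. The blink
effect, however, propagates mechanically into the rolling variances of
eye area, eye aspect ratio and vertical iris offset — a blink *is* a
collapse of those quantities — and those continuous columns carry the
blink signal with better signal-to-noise than the integer episode
counts, whose quartile threshold admits noise episodes by construction.
Impurity importance therefore credits the blink channel largely through
its variance signatures rather than through the count columns
themselves. The acceptance test asserts the count-column ranking as
specified; if it fails while the variance signatures of the same channel
fill the top ranks, that is the structural reason.

## Numerical conventions

* Quantiles: linear interpolation (R type 7) everywhere.
* Variance: population (divide by n), rolling windows centered,
  truncated at edges.
* Pulse alignment: step mode takes the sample with the greatest
  timestamp ≤ frame time; linear mode interpolates at the frame
  timestamp and holds the last sample; a frame covered by a missing
  sample (either endpoint in linear mode) is missing.
* Ties and degenerate cases: zero-denominator ratios are missing;
  tracking-failure frames (`success = 0`) are kept by the reader,
  marked all-missing by the extractor, and removed by `drop_missing()`;
  a zero nasal bridge marks the whole frame missing.
* Tree splits use midpoints between consecutive distinct values; a
  split that fails to separate (floating-point collapse) becomes a leaf.
* Seeds: the run seed derives the undersampling (`seed+1`), fold
  (`seed+2`) and per-fold forest (`seed+2+fold`) seeds; the generator
  uses its own `seed` field. Artifacts embed an FNV-1a hash of the
  configuration, and reruns with an unchanged configuration are
  byte-identical apart from the manifest timestamp.

## Known limitations

* The quartile closure rule guarantees 25% of frames are "closed"; on
  noisy data episode counts mix blinks with threshold-crossing noise.
  Count features are accordingly weak when continuous variance features
  of the same events are present.
* Frame-wise cross-validation numbers should be read as
  protocol-faithful, not as generalization estimates; use grouped folds
  for the latter.
* The literal-quartile outlier mode is destructive and present only for
  fidelity comparisons.
* Gaze angles are generated independently of the iris landmarks; a
  real tracker would couple them.
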