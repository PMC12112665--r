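---
title: "Emotion-weighted pain estimation from facial landmarks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion-weighted pain estimation from facial landmarks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painface)
```

This vignette documents the model implemented by `painface`, the parameters
that matter and their defaults, what the synthetic generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## Coordinate convention and canonical alignment

Input landmarks are image-normalized: x and y in [0, 1], origin at the
top-left, y pointing down, following the common face-mesh convention. All
displacement arithmetic happens after `align_landmarks()` maps a frame into
*canonical coordinates*: the two eye-anchor landmarks (outer eye corners,
indices 33 and 263 on the standard 468-point mesh, configurable) are placed
on a horizontal line exactly one unit apart with their midpoint at the
origin. The unit of every displacement is therefore the subject's
interocular (outer-canthal) distance, which removes image scale, in-plane
head rotation and translation. The transform is a similarity, so alignment
is idempotent and invariant under any in-plane similarity applied to the
input — both properties are tested to 1e-12 and 1e-9 respectively. The
pre-normalization interocular distance is kept as `scale_ref` so absolute
units can be recovered. Depth (z) is rescaled but not rotated; it is a
relative quantity in mesh output and is excluded from distances by default
(`use_z = FALSE`), because planar displacement is what the downstream
calibration is defined on.

Degenerate geometry (coincident eye anchors) is refused with a classed
error rather than producing a non-finite frame.

## From displacement to AU intensity

An AU zone is a configured set of mesh indices (`zone_table()` shows the
bundled default: between-brow cluster for AU1, infraorbital for AU6, nasal
sidewall for AU9, mouth corners for AU15, chin for AU17, periocular ring
for AU44, plus the PSPI auxiliaries AU4, AU7, AU10 and AU43). Published
AU systems rarely agree on exact indices, so the configuration file is the
single source of truth and user-replaceable; results that depend on zone
membership cannot be compared across systems without it.

Per-point displacements are calibrated linearly to the 0–5 FACS intensity
scale: `I = min(5 d / d_max, 5)`. `d_max` is the canonical-unit
displacement corresponding to a maximal (intensity 5) activation:

* default 0.25 interocular units for every AU. At a typical adult
  outer-canthal distance (~9 cm) this is ~2.3 cm, the rough magnitude of a
  maximal mouth-corner or brow action. Real deployments should calibrate
  per AU and per population; the default is a single realistic scale chosen
  once, not a fitted value.
* AU43 (eye closure) is scored 0/1 by thresholding at half its `d_max`,
  reflecting its binary definition in the PSPI scale.

Zone intensities are reduced to one scalar per AU by the zone maximum (the
strongest activation represents the region; a mean reduction is available).

## Pain scores and levels

Three scores are computed per frame:

* `pspi_ple()`: `AU4 + max(AU6, AU7) + max(AU9, AU10) + AU43`. The stated
  maximum of the PSPI scale is 15 although the raw sum of the stated input
  ranges is 16; the implementation keeps both readings behind
  `clamp = TRUE` (default, capped at 15) and `clamp = FALSE` (raw sum),
  and both behaviors are tested.
* `zone_max_ple()`: the sum of the six zone maxima, range [0, 30].
* `weighted_ple()`: the emotion-weighted score. *Hard* mode multiplies by
  the single detected emotion's weight; *soft* mode weights by the full
  expression distribution, `Ps * sum_e p_e w_e`. The weighting equation can
  be read either way (a sum over the seven categories versus a product with
  the detected category's weight); hard mode is the default because the
  per-frame algorithmic description resolves to the single-label product,
  and soft mode is provided as the faithful reading of the summation form.
  Soft-mode scores are bounded by `min(w) * Ps` and `max(w) * Ps`, with
  equality exactly for one-hot distributions.

The emotion–pain weights are constants: happiness 0.8, surprise 0.9,
neutrality 1.0, disgust 1.2, fear 1.4, anger 1.6, sadness 1.7. Negative
affect amplifies experienced pain relative to the facial display; positive
affect attenuates it.

Scores are binned into six ordinal levels. The thresholds are not part of
any published scale, so the default is the unopinionated choice:
equal-width bins 6, 12, 18, 24, 30 over the zone-max range, left-inclusive
(a score of exactly 6 is level 1), an exact-zero floor for level 0, and a
cap at level 5 for weighted scores that exceed 30. Weighted scores are
binned on the same thresholds as raw scores, so weighting can move a frame
across level boundaries — which is precisely its purpose.

## Expression classification

The classifier is deliberately transparent: a weighted sum of AU
intensities per emotion (`fer_scores()`), a temperature-1 softmax
(`to_distribution()`), and an argmax with ties broken by the canonical
category order (`classify()`). It is *not* a trained model, and the
package makes no claim that it reproduces any CNN classifier; any
user-supplied weight matrix of the same shape is accepted.

The default matrix is built from the prototype patterns used by the
synthetic generator (happiness {AU6}, surprise {AU1}, neutrality {},
disgust {AU9}, fear {AU1, AU44}, anger {AU44, AU17}, sadness
{AU15, AU17, AU1}) as **centered indicators**: emotion *e*'s row is 1 on
its k prototype AUs minus k/6 on all six. Two design points deserve
explanation:

* *Centering.* With plain 0/1 rows, any emotion whose prototype is a
  superset of another's (fear vs surprise) scores at least as high on the
  subset emotion's own prototype, and strictly higher as soon as
  measurement noise lifts every zone's intensity a little — the subset
  emotion would then never be predicted. Centered rows are orthogonal to a
  uniform intensity offset, so shared activation cancels. On noiseless
  prototypes both matrices classify 7/7; under noise only the centered one
  remains usable. `default_au_weights(centered = FALSE)` provides the raw
  indicator matrix.
* *The neutral gate.* A linear score without intercept is 0 for every
  emotion on an inactive face, and the declared tie-break (canonical
  order) would return happiness. `classify_expression()` therefore labels
  a frame neutral when the summed AU intensity falls below
  `neutral_gate = 0.25` (on the 0–5 scale, i.e. 5 % of one AU's range).
  The gate is the smallest mechanism that makes neutrality reachable; it
  is configurable and can be disabled.

## The synthetic generator

`simulate_faces()` exists so every stage is testable without any image
data. It emulates a balanced seven-expression corpus of neutral/activated
frame pairs:

* a deterministic canonical template (`make_face_template()`) with unit
  interocular distance and per-zone-point unit displacement directions;
* stratified emotion assignment (largest-remainder allocation, so a
  70-frame uniform dataset has exactly 10 frames per class);
* a per-frame pain amplitude uniform on [0, 5], applied multiplicatively
  to the emotion's prototype AU pattern; activation displaces each zone
  point by `(intensity / 5) * d_max` along its direction, exactly
  inverting the calibration — at zero noise the pipeline recovers the
  generated intensities, zone-max score, emotion and level to 1e-9
  (tested);
* isotropic Gaussian coordinate noise (standard deviation `sigma`, in
  interocular units) added to the active frame only; the neutral frame is
  the clean reference. Generated frames are already canonical, and the
  noise is defined in canonical units, so the pipeline consumes them
  without re-alignment.

With `confound_emotion = TRUE` the frame's *experienced* pain score is the
emotion weight times its displayed zone-max score — emotional context
amplifies (negative affect) or attenuates (positive affect) experienced
pain relative to the facial display. This is exactly the situation the
weighted estimator is built to correct, and `compare_estimators()` scores
all four estimators against that ground truth.

What the generator does **not** emulate: photorealistic appearance,
detector-specific error structure (real landmark errors are correlated and
pose-dependent, not isotropic), inter-subject anatomical variation,
temporal smoothness of real video, co-occurring AUs outside the prototype
patterns, and annotation noise. Passing tests therefore demonstrate
correctness of the computational pipeline and its statistical behavior
under the stated noise model — not clinical validity on real faces.

## Problem sizes and numerical choices

The test-suite and acceptance workloads use 70-frame datasets for
round-trip and determinism checks, 700 frames (100 per class) for the
estimator comparison, and 60-second single-emotion series for temporal
profiles; these sizes give stable class-wise percentages while keeping a
full run in the order of a minute. Exact identities are asserted to 1e-9
(alignment invariance, round-trip recovery) or 1e-12 (pure arithmetic);
comparisons against independent brute-force oracles (zone maxima, AUC as
the concordant-pair fraction, confusion tallies) are exact. All randomness
is seeded; a fixed seed makes the simulate → run → evaluate chain
byte-identical, which is tested on file digests.

Degenerate inputs are rejected with classed errors (`painface_*`):
non-finite coordinates, coincident eye anchors, empty zones, missing
calibration entries, non-ascending thresholds, out-of-range AU values.
Undefined evaluation ratios (a class with zero support) are reported as
missing values, never coerced to 0, so macro averages stay honest.

## Known limitations

* **Noise bias of the zone-max statistic.** The zone score takes a maximum
  over per-point displacements, and a maximum of noisy non-negative
  distances is positively biased: with per-coordinate noise sigma the
  expected zone intensity on an *inactive* zone is roughly
  `5 / d_max * E[max of k Rayleigh(sigma)]`, summed over six zones. At
  noise levels around 1 % of the interocular distance this bias reaches a
  sizeable fraction of a pain level under the default calibration. The
  bias inflates raw and weighted scores alike, but the weighted estimator
  multiplies it by the emotion weight, so under heavy landmark noise the
  weighting's advantage on emotion-confounded data shrinks and can invert
  — the acceptance script computes both estimators' accuracies at exactly
  this operating point. Reducing landmark jitter (temporal smoothing,
  detector averaging) or calibrating `d_max` generously relative to the
  noise floor restores the weighted estimator's advantage.
* The expression classifier is a linear stand-in with package-defined
  prototypes; real deployments should supply a weight matrix fitted to
  their detector and population.
* Zone membership, calibration and pain-level thresholds are conventions
  shipped as configuration, not clinically validated constants.
* Multi-face frames, face detection/tracking, and video decoding are out
  of scope; the package starts at landmark sets (a detector adapter is a
  single function `image -> landmark_set`).
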