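# painface

Emotion-weighted estimation of pain intensity from facial landmarks.

Pain assessment in patients who cannot self-report relies heavily on facial
expression. The Facial Action Coding System (FACS) decomposes expressions
into action units (AUs), and pain carries a well-characterized AU signature:
brow lowering/raising, cheek raising, nose wrinkling, lip-corner depression,
chin raising, squinting and eye closure. `painface` implements a landmark
displacement pipeline for scoring that signature and an emotion-aware
weighting that separates pain-driven facial movement from emotion-driven
movement: a grimace during sadness and the same grimace during happiness do
not imply the same experienced pain.

The package is aimed at researchers in automated pain assessment and
affective computing who work with dense face-mesh landmarks (the standard
468-point topology, e.g. from any face-mesh detector) rather than raw
pixels. Everything downstream of landmark detection is provided: image
preprocessing helpers, canonical alignment, AU-zone intensity extraction,
expression classification, pain scoring, a fully synthetic ground-truth
generator, and an evaluation harness.

## The model

Landmarks are canonically aligned (eye anchors horizontal, unit interocular
distance, centered), so displacements are comparable across faces and
poses. For each AU zone *z* (a configured set of mesh indices), the
displacement of point *i* between the neutral and activated frame is

    d_i = sqrt((x_a - x_n)^2 + (y_a - y_n)^2)

and is calibrated linearly to a 0–5 FACS-style intensity,
`I = min(5 d / d_max, 5)` (AU43, eye closure, is binary). Three pain scores
are computed:

* **PSPI** (Prkachin–Solomon pain intensity):
  `AU4 + max(AU6, AU7) + max(AU9, AU10) + AU43`, capped at the scale
  maximum of 15 (the raw sum can reach 16; the cap is configurable).
* **Zone-max score** `Ps` over the six pain zones:
  `max(AU1) + max(AU6) + max(AU9) + max(AU15) + max(AU17) + max(AU44)`,
  range 0–30.
* **Emotion-weighted score** `PLEw = Ps × w(e)`, where the expression
  classifier assigns the frame one of seven categories with weights
  happiness 0.8, surprise 0.9, neutrality 1.0, disgust 1.2, fear 1.4,
  anger 1.6, sadness 1.7. A soft mode weights by the full expression
  probability distribution instead of the argmax label.

Scores are binned into six ordinal levels (no pain, mild, moderate, severe,
very severe, worst pain) with equal-width default thresholds 6, 12, 18, 24,
30 over the zone-max range.

## Worked example

```r
library(painface)

tpl <- make_face_template(seed = 1)                     # canonical synthetic face
grimace <- apply_activation(tpl, c(AU15 = 4, AU17 = 4, AU1 = 4),
                            frame_id = "grimace")
compute_pain(tpl$points, grimace)
#> <pain_score> frame 'grimace': ps = 12.000, plew = 20.400 (sadness, w = 1.7), level 4 (very severe)
```

The lip-corner/chin/inner-brow pattern scores 4 in three of the six zones
(`ps = 4 + 4 + 4 = 12`, i.e. moderate on the raw scale), is classified as a
sadness-type expression and is therefore weighted by 1.7: the weighted
score 20.4 falls in level 4, "very severe". `tidy()` returns the same
record as a one-row tibble for pipelines over many frames
(`estimate_pain()`).

Synthetic datasets with known ground truth drive the evaluation harness:

```r
d <- simulate_faces(n_frames = 70, sigma = 0.005, seed = 1,
                    confound_emotion = TRUE)
compare_estimators(d)
#> # A tibble: 8 × 6
#>   class          n   ple  plew  plez plewz
#>   <chr>      <int> <dbl> <dbl> <dbl> <dbl>
#> 1 happiness     10 100   100   100     100
#> 2 surprise      10 100   100    90     100
#> 3 neutrality    10   0     0     0       0
#> 4 disgust       10 100   100   100      80
#> 5 fear          10  10    10   100      70
#> 6 anger         10  40    40    60      80
#> 7 sadness       10  10    10    20      60
#> 8 average       70  51.4  51.4  67.1    70
```

Columns are exact pain-level accuracies (%) per true expression class for
the four estimators: PSPI (`ple`), weighted PSPI (`plew`), zone-max
(`plez`) and emotion-weighted zone-max (`plewz`). On this dataset the
experienced pain of each frame is its displayed zone-max score amplified by
the emotion weight, so the weighted estimator recovers it best.
`temporal_profile()` + `autoplot()` produce the per-second raw-vs-weighted
score curves for single-subject series.

## Notes

* The mapping from zone indices to AUs ships as a versioned JSON config
  (`inst/extdata/zone_config_mesh468.json`) and is user-replaceable; zone
  membership is the single largest source of variation between face-mesh
  AU systems.
* The displacement-to-intensity calibration (`d_max`, default 0.25
  interocular units for every AU) must be recalibrated for real deployments.
* See the methods vignette (`vignettes/pain-estimation.Rmd`) for the model
  assumptions, parameter rationale, and known limitations — including the
  positive bias of zone-maximum scores under landmark noise.
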