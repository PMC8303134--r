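---
title: "Methods: Graf-angle screening, synthetic phantoms and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Graf-angle screening, synthetic phantoms and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grafscreen)
```

## The measurement model

Graf-method hip ultrasonography reads three lines off a coronal
standard-plane image of the infant hip: the *baseline* along the vertical
ilium, the *bony roof line* from the lower edge of the iliac bone to the
acetabular bone edge (the bony rim), and the *cartilage roof line* from the
bony rim to the tip of the acetabular labrum. The package represents the
minimal information needed to draw those lines as a five-point
`landmark_set`:

- `check_upper`, `triradiate` — the two check-angle points along the iliac
  wing. The distal one coincides with the tri-radiate cartilage point, so
  the baseline is the line through these two points.
- `lower_ilium`, `bone_edge` — the bony roof line.
- `bone_edge`, `labrum_end` — the cartilage roof line (sharing the rim).

Angles between undirected lines are computed as
`acos(|u·v| / (|u||v|))`, which is symmetric in line order and point order
and always lies in [0°, 90°]. Alpha is the baseline/bony-roof angle and beta
the baseline/cartilage-roof angle. A hip is classified *normal* when
α ≥ 60° — the boundary is inclusive because Graf type I is defined by
α ≥ 60°; the dichotomy, not the full Graf subtype ladder (IIa–IV), is what
the screening comparison uses.

The *check angle* quantifies whether the image is a usable standard plane:
it is the signed angle between the baseline and the image vertical (x
rightward, y downward, 0-based sub-pixel pixel coordinates), positive when
the distal wing rotates toward +x. The reference axis is the image vertical
because standard-plane images are documented vertically oriented; the sign
is retained for diagnostics but the appropriateness gate uses the magnitude:
an image passes when |check| ≤ 5°, boundary inclusive ("within ±5°" read
plainly). Images failing landmark detection by either rater are
`fail_detection`; detectable images failing the double check gate are
`inappropriate_check_angle`; the rest are `appropriate`, and only those
enter the alpha/beta agreement analysis.

## The synthetic phantom

No public set of annotated infant hip ultrasounds exists, so the package
generates phantoms with exact ground truth. `generate_landmarks()` inverts
the geometry: given requested (α, β, check), it places the baseline at the
check angle from vertical, the bony roof line at 180° − α from the distal
baseline direction, and the cartilage roof line at 180° − β, so recomputing
the three angles from the returned landmarks reproduces the request to
floating-point precision (the round-trip tests assert 10⁻⁶ degrees).

`phantom_truth()` rasterises three structures, chosen as the minimal
anatomy every landmark can be recovered from:

- *ilium*: a flat-ended band of half-width 0.020·S (S = min image side)
  along the baseline segment;
- *acetabular roof*: a band of half-width 0.016·S from `lower_ilium` to
  `bone_edge`, with `lower_ilium` placed 0.08·S distal of the tri-radiate
  point so the two bright bands never touch at small alpha;
- *labrum*: an ellipse (semi-axes 0.06·S × 0.018·S) whose distal tip is the
  labrum landmark, 0.18·S from the rim — a long cartilage-roof lever keeps
  beta insensitive to sub-pixel tip error.

Intensities default to bone 200 / background 40 (8-bit gray). The paper
trail for real acquisitions records no intensity statistics, so these
contrasts are free design choices, not calibrated values. Noise is a
first-order ultrasound speckle surrogate: multiplicative log-normal
(`exp(N(0, σ))`, σ = `speckle_sigma`, default 0.12) times the ideal image,
plus additive Gaussian noise with SD 5σ; σ = 0 yields a bit-exact noise-free
image and identical seeds yield bit-identical images. What the phantom does
*not* emulate: attenuation and shadowing, correlated speckle texture, probe
geometry, anatomical shape variation beyond the three parametrised angles.
Passing tests therefore demonstrate the pipeline's correctness and
noise-robustness on controllable geometry, not clinical-grade performance.

`generate_cohort()` draws per-image true angles from truncated normals
defaulting to the study population summary (α 64.117 ± 7.12, β
40.679 ± 8.71, check 0 ± 3, all in degrees) and simulates paired readings:
each detectable reading is truth plus independent Gaussian noise with SD
`rater_noise_sd`/√2 per rater, so the AI−human difference has SD
`rater_noise_sd` (default 4.5°, matching the reported between-rater
difference SD). A `detect_failure_rate` fraction per rater is flagged
undetectable.

`reference_cohort()` is the deterministic 921-image fixture whose
detectability flags and check-angle gates reproduce the published screening
margins (542/555/512 detectable; 320/49/49/94 gate table); angle values are
normal-quantile spreads around the population means so the object is
identical on every call without touching the RNG.

## The classical detector

`segment_structures()` thresholds at an intensity quantile (default 0.85 —
bone occupies a few percent of the frame, so the bright tail isolates it),
labels connected components (EBImage), drops components below
`max(9, 4·10⁻⁴·W·H)` pixels, and assigns structures geometrically: the
ilium is the largest elongated (≥ 2.5) component within 45° of vertical;
the acetabular roof is the component nearest the ilium's distal axis
endpoint; the labrum is the component nearest the roof's lateral endpoint.
Per-structure confidence is the component's mean-intensity contrast against
the whole-frame mean, scaled to [0, 1]; an image is detectable when all
three structures are found with confidence ≥ 0.5 and all five landmarks
extract. The 0.5 floor operationalises an "observable" criterion that has
no published quantitative definition.

`extract_keypoints()` reads landmarks off principal axes: each endpoint is
the centroid of the pixels within 1.5 px of the extreme axial projection,
projected back onto the axis — the perpendicular component of an end-cap
centroid is discretisation jitter and would tilt the derived lines, so it
is removed. The labrum tip is the labrum's principal-axis endpoint lying
farther from the baseline (a raw farthest-from-baseline pixel rule biases
the tip by several pixels whenever the labrum axis is oblique to the
baseline normal). On noise-free phantoms this recovers every landmark
within ~1.7 px and alpha/beta within 1° (asserted at ≤ 2° across 100
phantoms spanning α 40–80°).

`masks_to_stage1()` renders any mask set as white (255) on black (0); it is
idempotent on masks derived from its own output, and `detect()` composes
the three stages, encoding failure in the result rather than raising.

## The trainable detector

The two-stage training protocol is preserved at desk scale: stage 1 learns
the image → white-on-black mapping, stage 2 learns the five keypoints from
stage-1 outputs. The configured protocol (default 40,000 steps, validation
every 1000, SGD with learning rate 0.01, weight decay 10⁻⁴, batch 10,
augmentation: shift ±5%, scale 80–100%, rotation ±15°, brightness 75–100%,
Gaussian noise) is fully representable; tests exercise a 500-step toy run.

The backbone is deliberately small because no deep-learning framework is a
package dependency: stage 1 is a per-pixel logistic model over five local
features (intensity, 3×3 and 7×7 box means, gradient magnitude, bias)
trained on balanced foreground/background pixel samples; stage 2 is a
linear regressor from an 8×8 mean-pooled stage-1 image to the ten
normalised landmark coordinates. Keypoints are regressed as pooled linear
coordinates rather than heatmaps: at 64×64 toy scale the coordinate head
trains in seconds, is exactly reproducible, and satisfies the contract that
training strictly reduces held-out landmark error versus the untrained
(randomly initialised) baseline. Both stages keep the best-validation
checkpoint (15% held-out split). Loss functions (cross-entropy, squared
error) and plain SGD without momentum are free choices; nothing about them
is tuned to a reference system.

## Agreement statistics

On the 2×2 check-gate table (a = both OK, b = AI-only OK, c = human-only
OK, d = both error): percent agreement 100(a+d)/n, positive percent
agreement 2a/(2a+b+c), and Cohen's κ = (p₀ − p_e)/(1 − p_e) with the
Fleiss–Cohen–Everitt asymptotic variance for its CI. The published κ CI for
the reference table is internally inconsistent as printed, so the package
documents its own asymptotic interval and does not target the printed one.

Continuous agreement uses ICC(A,1) — two-way random effects, absolute
agreement, single measurement — because two raters measure the same images
and a systematic offset between them should count against agreement; the
absolute-agreement form strictly decreases as a constant offset grows,
which the tests assert. The CI follows McGraw & Wong; interpretation uses
Cicchetti's bands (< 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, ≥ 0.75
excellent), mapping 0.764 → excellent and 0.743 → good. MAD is the mean
absolute AI−human difference (mean-based, not median); the <5° discrepancy
fraction uses a strict inequality ("less than 5°") while the 60°
concordance inherits the inclusive classification boundary.

## Numerical choices and degenerate inputs

- Angles are computed in double precision and reported to 3 decimals in
  exports; classification boundaries (60°, ±5°) are inclusive.
- Degenerate lines (coincident points), empty masks, empty cohorts,
  all-constant ICC input and χ-less κ (p_e = 1) raise descriptive errors;
  segmentation shortfalls return `detectable = FALSE` instead of raising.
- All randomness flows through explicit seeds (`with_seed` restores global
  RNG state), making images, cohorts and training runs bit-reproducible.
- Problem sizes in the tests — 100-spec round trips, 100-phantom accuracy
  sweeps, 50-phantom detectability counts, n = 2000 ICC recovery, 40-image
  500-step toy training — were chosen so the full suite exercises every
  contract at statistically meaningful scale while remaining a desk-scale
  run.

## Known limitations

- The phantom is a geometric surrogate; detector performance on it upper-
  bounds nothing about clinical images.
- The published clinical reliability values (ICC 0.764/0.743, MAD 3.47/4.50,
  74.7% within 5°, 84.3% concordance) require the unpublished per-image
  measurements of the original 320-image reading study and are therefore
  not reproduction targets; the package instead verifies its statistics on
  constructed fixtures and simulations with known truth.
- The DICOM layer covers explicit-VR little-endian uncompressed grayscale
  objects — sufficient for the anonymising conversion path it exists for —
  not encapsulated transfer syntaxes, sequences or multi-frame cine loops.
- Graf subtype classification from beta is out of scope; only the 60° alpha
  dichotomy is implemented.
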