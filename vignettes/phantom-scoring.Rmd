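---
title: "Scoring mammography accreditation phantoms: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mammography accreditation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring problem

Accreditation phantoms for mammography embed sixteen artificial lesions in
a 4×4 grid: six nylon fibers, five groups of six simulated
microcalcifications ("specks"), and five low-contrast masses, each family
in strictly decreasing size. A reader grades every lesion 0.0, 0.5 or 1.0
by visibility at the correct location, and the phantom passes when the
sequential feature totals reach at least 4.0 (fibers), 3.0 (specks) and
3.0 (masses). The *sequential* total walks a family from its largest
lesion: each consecutive 1.0 adds a full point, the first lesion that does
not earn 1.0 contributes its own value and stops the walk, and smaller
lesions are ignored. An auxiliary N/A label marks lesions that are visible
but below the 0.5 criterion; N/A contributes nothing to a total (a 0.5
contribution is available as a sensitivity option, `na_value = 0.5`).

`phantomqa` implements this protocol three times over — as a generative
model with known ground truth, as deterministic rule scorers, and as a
trainable classifier — so each implementation can be checked against the
others.

## The synthetic phantom model

Real phantom submissions cannot be redistributed, so the package renders
stylized radiographs whose ground truth is known by construction. A scene
is composed of an acrylic body (300×280 render px, intensity 0.45 above an
air level of 0.02), a 240×240 px gel insert (intensity 0.58) holding the
4×4 lesion grid in 60 px cells, and optional disc and text artifacts on
the body below the insert. The scene is blurred by a Gaussian PSF
(`blur_sigma`, default 0.8 px), oriented (quarter turns plus a fine angle)
and translated, degraded with seeded Gaussian detector noise
(`noise_sigma`, default 0.01 in normalized scene units), quantized to 12
bits and given MONOCHROME1 or MONOCHROME2 polarity.

Lesion visibility is parameterized the way the scoring rules read it:

* a **fiber** renders the axis fraction `[0, visibility]` minus a gap at
  each break position (gap width `max(0.08, 5 px / length)` of the fiber
  length, so a rendered gap never falls below the blur scale);
* a **speck group** renders six dots at fixed cluster positions with
  per-speck opacities in [0, 1];
* a **mass** renders a disc whose contour is circular over the fraction
  `visibility` of its angle and stepped inward to 0.6 of the radius over
  the rest. The dent depth is deliberately deep enough (40 %) that the
  smallest mass's non-circular arc remains resolvable after blur and
  resampling; shallower dents drown in the ~1 px contour-measurement
  noise at a 9 px radius.

Two geometric choices are load-bearing. First, the insert is exactly
240 px so the 224×224 standardization maps grid cells exactly onto
56 px tiles. Second, the body sits flush near the bottom of the canvas
(10 px margin) with side margins of 40 px, so the image side nearest the
phantom is unambiguous for any sampled translation (|offset| ≤ 8 px by
default) — mirroring real acquisitions, where the phantom abuts the
detector edge. Earlier margins that allowed near-ties produced occasional
quarter-turn misdetections, which is a property of the scene geometry, not
of the detector.

The default `sampling_distribution()` draws each lesion independently:
fully visible with probability 0.8, absent with 0.05, partial otherwise —
imitating the strong full-score imbalance of real submissions (roughly
80 % of lesions earn 1.0). Nuisances are sampled per phantom: noise
0.005–0.02, blur 0.6–1.0 px, fine rotation ±3°, a quarter-turn orientation
with probability 0.15, translation ±8 px, MONOCHROME1 with probability
0.1.

What the generator does **not** emulate: scanner MTF/NPS, film
digitization artifacts, scatter, geometric distortion, mislocated or
mis-oriented lesions, and phantom-model differences. Passing tests
therefore demonstrate the pipeline's correctness on images whose
degradations are blur, noise, orientation, polarity and intensity scale —
not clinical-grade robustness.

## Standardization pipeline

1. **Photometric normalization** (`to_monochrome2`): MONOCHROME1 is
   complemented against its dynamic range; an unknown tag is resolved by a
   border heuristic (in MONOCHROME2 the border/air is darker than the
   interior).
2. **Localization** (`locate_phantom`): Otsu's threshold on a 256-bin
   rescaled histogram; morphological closing consolidates speckle; the
   largest connected component wins, ties broken by the lowest centroid.
   The image side nearest the component's bounding box determines the
   quarter turns that move the phantom to bottom-center (bounding-box gaps
   are used rather than center-of-mass distances, which are degenerate for
   near-centered phantoms). A sparse but widespread foreground — the
   signature of an image that is already a lesion field — short-circuits
   to a full-frame region, which is what makes the pipeline idempotent.
3. **Initial crop** (`align_and_crop`): the component bounding box plus a
   2 % margin, removing borders, text bands and black margins.
4. **Insert crop** (`crop_lesion_area`): a fine-rotation search (±5°,
   1° coarse then 0.1° refinement, evaluated on a 2× decimated copy)
   maximizes the edge sharpness of the row/column mean profiles; the
   insert borders are the strongest rising/falling profile transitions
   (6 % boundary zone excluded; prominence floor 0.025 of the profile
   range). The search-and-crop only runs when the central region is
   clearly brighter than the border band — an insert-only image passes
   through unchanged.
5. **Normalization and resize** (`normalize_and_resize`): bilinear resize
   to 224×224 first, then the min/max window over the central rhombus
   (vertices at the edge midpoints, which excludes corner outliers such as
   marker discs), affine mapping and clipping to [0, 1]. Resizing before
   windowing keeps the operation idempotent: the resampled image attains
   its window extremes exactly, so a second pass is an identity within
   interpolation tolerance. It also makes the output exactly invariant to
   affine intensity rescans `a·x + b`.

Degenerate inputs fail with a structured report naming the stage: a flat
image or an absent component fails localization; a flat rhombus window
fails normalization.

## Rule-based scoring

The rule scorers read each 56×56 tile at the geometry the layout map
prescribes, with measurements chosen for robustness to the ≤1 px shifts
and double interpolation the pipeline can introduce:

* **fibers** — a perpendicular-max line probe along the expected axis
  (81 samples, ±3 px offsets); a sample is covered when it exceeds 0.4 of
  the calibrated nominal peak (or 3× the tile noise). The longest covered
  run maps to the score; "complete" is `run ≥ 0.92`, absorbing endpoint
  blur while staying above the longest run any rendered break permits.
* **specks** — background-subtracted flux in a window at each expected
  position (flux, unlike peak height, is conserved under blur and
  resampling); opacity is flux relative to the calibrated full-opacity
  flux, with the detectability floor at 0.3.
* **masses** — threshold segmentation at the expected location, then a
  subpixel radial contour: 72 rays, each crossing located by linear
  interpolation at the half-plateau level. The circle center is refined by
  an iterated Kasa least-squares fit on the outer contour cluster (a
  dented contour otherwise biases the centroid and imprints a spurious
  first-harmonic wobble on the radii). A ray is circular when its radius
  deviates from the fitted radius (90th percentile) by less than 10 % (or
  0.9 px, the pixel-noise floor); the circular fraction above 3/4 earns
  the full point.

Nominal peaks, fluxes and areas come from `rules_calibration()`: a single
memoized render of a fully visible, noiseless reference phantom at default
blur, measured by the same functions the scorer uses.

Pixel measurements have finite resolution, so exact agreement with the
parameter-derived ground truth is claimed only outside declared
**ambiguity bands** around each decision boundary, fixed up-front as part
of the scoring protocol: fiber longest-run in (0, 0.18) ∪ (0.42, 0.58) ∪
(0.88, 0.995); speck opacity (after the phantom's normalization-window
gain) in (0.22, 0.38); mass contour fraction in (0.68, 0.82) or below
0.15. The acceptance suite verifies exact agreement on a 500-phantom
noiseless sweep outside these bands; agreement inside them is genuinely
ambiguous at this resolution and is neither claimed nor asserted.

## The dual-output learned scorer

Each tile receives two sigmoid outputs: `p_exist` (score 0.5 or 1.0
versus 0.0) and `p_abnormal` (score 0.5 versus 1.0). Labels encode
1.0 → [1, 0], 0.5 → [1, 1] and 0.0 → [0, ·] with the abnormality loss
**masked**, because an absent lesion offers no basis for abnormality
assessment; the mask provably zeroes the abnormality gradient on those
samples (the suite checks this against finite differences). The loss is a
per-output binary focal loss, `-w (1-p_t)^γ log p_t`, with γ = 2 by
default and class weights proportional to inverse class frequency; at
γ = 0 and unit weights it reduces to mean binary cross-entropy, which the
tests verify against a hand-computed batch.

The default backbone is a small fully-connected network (`"mlp:32-16"`,
about 100 K parameters, ReLU hidden layers) written with exact analytic
gradients. A fully-connected default — rather than a small convolutional
network — was chosen because the hand-derived backward pass is short
enough to verify line by line and directly yields the input gradients the
saliency maps and masking checks need; the descriptor string leaves room
for other backbones. The consequence, documented as a limitation, is that
gradient saliency concentrates on the lesion region less sharply than a
convolutional architecture would: the suite asserts a saliency *density*
ratio inside the dilated lesion mask (> 1.2× the tile average) rather
than a majority of the total mass.

Optimization is plain SGD with learning rate 5e-3 and weight decay 1e-5
by default, following the established QA-model training protocol; 200 epochs are
available by configuration but the package defaults to 30. The desk-scale
benchmark in the acceptance suite trains on ~2,000 easy tiles (135
phantoms, noise 0.005, no augmentation, learning rate 0.05) for 30 epochs
per seed — sizes chosen to make a three-seed average complete comfortably
on one CPU. Augmentation (flips, shifts ≤ 10 %, rotation ≤ 10°, rescale
0.9–1.1, blur ≤ 1 px or noise) is implemented and seeded but off in that
benchmark; magnitudes are package defaults since only the kinds are
prescribed by the protocol.

Decision thresholds are chosen to maximize the per-output F1
(`pick_thresholds()`; ties to the smallest threshold, degenerate labels
fall back to 0.5 with a warning). `interpretation_sweep()` re-renders one
lesion across a manipulation (fiber break position, fiber length, joint
speck count/opacity, mass deformation, mass rescale) and records both
probabilities with threshold-crossing annotations, reproducing the
probe-the-model experiments as a framework.

## Evaluation protocol

Lesion-level metrics are three-class confusion matrices with per-class
precision/recall (zero-division reported as 0 with a flag) and **macro**
F1 over the score classes — the conventional average for imbalanced
three-class reports; the existence ROC treats 0.5/1.0 as positive, the
abnormality ROC excludes 0.0 tiles and treats 0.5 as positive; AUC is
trapezoidal and is tested against the exhaustive concordant-pair fraction
and against an independent ROC implementation. Bootstrap intervals are
percentile intervals over case-level resamples (the case, not the tile,
is the exchangeable unit — tiles within a phantom are correlated), 10,000
resamples by default, seeded, with undefined resamples redrawn and
counted. The stratified split uses largest-remainder rounding per stratum,
which reproduces the reference 70/10/20 allocation of a 4,029/1,784
pass/fail corpus exactly.

## Known limitations

* The phantom geometry is stylized, not metrologically faithful to any
  commercial phantom model; absolute sizes and contrasts are package
  conventions.
* Mislocated or mis-oriented lesions are out of scope; the generator
  always places lesions correctly and the rule scorers assume it.
* The learned scorer is a desk-scale model for protocol verification, not
  a replacement for a large pretrained backbone; its headline numbers on
  real submissions are unknown by construction.
* Flipped images (mirror orientations) are not detected or recovered;
  they fail or mis-score as they would in the original pipeline.
* The pipeline's insert detection expects a gel insert brighter than the
  surrounding body; phantom models with addendum parts or magnetic
  adhesive components are unsupported.
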