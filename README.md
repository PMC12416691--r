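# phantomqa

Automated quality-assurance scoring of ACR-style mammography accreditation
phantom radiographs.

Mammography QA programs require institutions to submit phantom radiographs
for periodic review. The accreditation phantom embeds 16 artificial lesions
in a 4×4 grid — six nylon **fibers**, five **speck groups** of six
microcalcification-like dots, and five low-contrast **masses**, each family
in decreasing size — and trained readers grade every lesion 0.0 (absent),
0.5 (partially visible) or 1.0 (fully visible at the correct location),
with an auxiliary **N/A** label for lesions visible but below the 0.5
criterion. `phantomqa` automates this reading end to end and, because real
submissions cannot be redistributed, ships a synthetic phantom renderer
with programmatically known ground truth so that every stage is testable.

## What the package does

* **`synth`** — renders stylized phantom radiographs (12-bit,
  MONOCHROME1/2, configurable blur/noise/orientation/translation, disc and
  text artifacts) from a `phantom_spec()`, together with the ground-truth
  scores its parameters imply under the guideline rules
  (`derive_guideline_score()`).
* **`preprocess`** — the four-stage standardization pipeline
  (`run_pipeline()`): photometric normalization to MONOCHROME2; phantom
  localization by Otsu thresholding and connected components plus
  re-orientation to bottom-center; lesion-area cropping by line-profile
  analysis with a fine-rotation search; intensity normalization over the
  central rhombus window and bilinear resize to 224×224; and division into
  sixteen 56×56 lesion tiles (`split_grid()`).
* **`rules`** — deterministic guideline scorers per lesion type
  (`score_fiber()`, `score_specks()`, `score_mass()`): longest continuous
  fiber run (1.0 only for a complete, unbroken fiber; 0.5 above half),
  count of distinctly visible specks (1.0 at ≥5 of 6, 0.5 at 2–3), and the
  circular contour fraction of a mass (1.0 strictly above 3/4).
* **`learned`** — a trainable dual-output scorer: each tile yields
  `p_exist` (a lesion is present) and `p_abnormal` (present but
  insufficient for a full point). Labels encode 1.0 → [1, 0], 0.5 → [1, 1],
  0.0 → [0, ·] with the abnormality loss masked; training minimizes a
  focal loss with inverse-proportion class weights under SGD
  (`train_scorer()`), and first-order gradient saliency maps plus
  controlled manipulation sweeps (`interpretation_sweep()`) expose what
  the model keys on.
* **`qualify`** — the national sequential-total rule (`feature_total()`):
  walk each family from the largest lesion, add 1.0 per consecutive full
  score, add the first non-1.0 score and stop; a phantom qualifies iff the
  totals reach **4.0 / 3.0 / 3.0** (fibers / specks / masses).
  `qualify_early_stop()` is the call-sparing equivalent.
* **`evaluate`** — three-class confusion metrics and macro-F1,
  existence/abnormality ROC with trapezoidal AUC, F1-maximizing decision
  thresholds, percentile bootstrap CIs, largest-remainder stratified
  splits, and a hierarchical lesion/feature/phantom report
  (`evaluate_system()`).

## Worked example

Render a phantom with three deliberately degraded lesions — fiber-2 broken
at its midpoint, specks-3 with three of six specks, mass-2 with only 60 %
of its contour circular — standardize it (here rendered rotated 90°), and
score it with the rule scorer:

```r
library(phantomqa)
lay <- phantom_layout()

lesions <- full_visibility_lesions(lay)
lesions[[2]]  <- lesion_params("fiber", 2, visibility = 1,
                               break_positions = 0.5, layout = lay)
lesions[[9]]  <- lesion_params("specks", 3,
                               visibility = c(1, 1, 1, 0, 0, 0), layout = lay)
lesions[[13]] <- lesion_params("mass", 2, visibility = 0.6, layout = lay)

spec <- phantom_spec(lesions, noise_sigma = 0.01, rotation = 90, seed = 42)
r    <- render_phantom(spec, lay)
std  <- run_pipeline(r$image)
sc   <- score_phantom(split_grid(std, lay), layout = lay)
sc$scores
#>  [1] 1.0  NA 1.0 1.0 1.0 1.0 1.0 1.0 0.5 1.0 1.0 1.0 0.5 1.0 1.0 1.0
qualify_phantom(sc$scores, lay)
#> fiber: 1.0  specks: 2.5  mass: 1.5  -> Unqualified
```

The broken fiber leaves no continuous run above half its length, so it is
graded N/A; under the sequential rule the fiber total stops at rank 2 with
1.0 < 4.0 and the phantom is disqualified — exactly the verdict implied by
the generator's ground truth (`r$truth`). The same images can be produced
and scored from the shell:

```sh
exec/phantomqa synth --n 25 --out phantoms --seed 1
exec/phantomqa run --in phantoms --out results --scorer rules
```

Training the dual-output scorer on synthetic tiles and probing it:

```r
tiles  <- ...           # subimages + labels, e.g. from sample_dataset()
scorer <- train_scorer(tiles$subs, tiles$scores, train_config(epochs = 30))
interpretation_sweep(scorer, cell = 1, "fiber_length", steps = 9)
```

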