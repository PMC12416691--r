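# Shared fixtures, built lazily and cached for the whole test session.

.fixtures <- new.env(parent = emptyenv())

test_layout <- function() {
  if (is.null(.fixtures$layout)) .fixtures$layout <- phantom_layout()
  .fixtures$layout
}

test_calib <- function() {
  if (is.null(.fixtures$calib))
    .fixtures$calib <- rules_calibration(test_layout())
  .fixtures$calib
}

# noiseless, unrotated full-visibility phantom and its standardized image
nominal_phantom <- function() {
  if (is.null(.fixtures$nominal)) {
    spec <- phantom_spec(noise_sigma = 0, seed = 2)
    r <- render_phantom(spec, test_layout())
    std <- run_pipeline(r$image)
    .fixtures$nominal <- list(spec = spec, render = r, std = std)
  }
  .fixtures$nominal
}

# window gain of a processed phantom relative to the calibration reference
window_gain <- function(std, spec) {
  test_calib()$window_range /
    (diff(std$provenance$window) / (2^spec$bit_depth - 1))
}

# subimage tiles + ground-truth labels from the fast render path
gen_label_tiles <- function(n_phantoms, seed, noise = 0.005) {
  lay <- test_layout()
  specs <- sample_specs(n_phantoms, seed = seed, noise_sigma = noise,
                        rotation = 0, translation = c(0L, 0L))
  subs <- list(); scores <- numeric(0); cells <- integer(0)
  for (s in specs) {
    tl <- split_grid(render_standardized(s, lay), lay)
    gt <- vapply(s$lesions, derive_guideline_score, 0, layout = lay)
    keep <- !is.na(gt)
    subs <- c(subs, tl[keep])
    scores <- c(scores, gt[keep])
    cells <- c(cells, which(keep))
  }
  list(subs = subs, scores = scores, cells = cells)
}

# desk-scale training configuration: small backbone, no augmentation,
# 30 epochs on easy (high-contrast, low-noise) synthetic tiles
desk_config <- function(seed) {
  train_config(epochs = 30L, learning_rate = 0.05, batch_size = 64L,
               augment = NULL, backbone = "mlp:32-16", seed = seed)
}

# one trained scorer per seed, with its held-out set, cached
demo_scorer <- function(seed = 1L) {
  key <- paste0("scorer_", seed)
  if (is.null(.fixtures[[key]])) {
    tr <- gen_label_tiles(135, seed = 1000 + seed)
    va <- gen_label_tiles(25, seed = 2000 + seed)
    sc <- train_scorer(tr$subs, tr$scores, desk_config(seed))
    pr <- predict(sc, va$subs)
    sc$thresholds <- pick_thresholds(pr, va$scores)[c("t_exist", "t_abnormal")]
    .fixtures[[key]] <- list(scorer = sc, val = va, train = tr,
                             val_pred = pr)
  }
  .fixtures[[key]]
}

# brute-force longest-run oracle on a fine discretization of the fiber axis
brute_force_longest_run <- function(visibility, breaks, gap, n = 10000) {
  t <- (seq_len(n) - 0.5) / n
  on <- t <= visibility
  for (b in breaks) on[t > b - gap / 2 & t < b + gap / 2] <- FALSE
  r <- rle(on)
  if (!any(r$values)) 0 else max(r$lengths[r$values]) / n
}

score_equal <- function(a, b) {
  (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
}
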