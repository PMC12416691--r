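test_that("guideline scoring of parameters follows the visibility rules", {
  lay <- test_layout()
  # specks: counts of distinctly visible specks map to the score bands
  mk <- function(op) lesion_params("specks", 1, visibility = op, layout = lay)
  expect_equal(derive_guideline_score(mk(c(1, 1, 1, 1, 1, 0))), 1.0)
  expect_equal(derive_guideline_score(mk(rep(0, 6))), 0.0)
  expect_equal(derive_guideline_score(mk(c(1, 1, 1, 0, 0, 0))), 0.5)
  expect_equal(derive_guideline_score(mk(c(1, 0, 0, 0, 0, 0))), 0.0)
  # exactly 4 visible specks: full credit by default, 0.5 by configuration
  four <- mk(c(1, 1, 1, 1, 0, 0))
  expect_equal(derive_guideline_score(four), 1.0)
  expect_equal(derive_guideline_score(four,
                                      scoring_config(speck_four = 0.5)), 0.5)
  # opacities below the detectability floor do not count
  expect_equal(derive_guideline_score(mk(c(1, 1, 1, 1, 1, 0.1))), 1.0)
  expect_equal(derive_guideline_score(mk(rep(0.1, 6))), 0.0)
  # fiber: full visibility without breaks is the only way to 1.0
  expect_equal(derive_guideline_score(
    lesion_params("fiber", 1, visibility = 1, layout = lay)), 1.0)
  expect_equal(derive_guideline_score(
    lesion_params("fiber", 1, visibility = 0.8, layout = lay)), 0.5)
  expect_equal(derive_guideline_score(
    lesion_params("fiber", 1, visibility = 0, layout = lay)), 0.0)
  short <- lesion_params("fiber", 1, visibility = 0.3, layout = lay)
  expect_true(is.na(derive_guideline_score(short)))
  expect_equal(derive_guideline_score(
    short, scoring_config(fiber_short_na = FALSE)), 0.0)
  # mass: contour fraction over three quarters for the full point
  expect_equal(derive_guideline_score(
    lesion_params("mass", 1, visibility = 0.9, layout = lay)), 1.0)
  expect_equal(derive_guideline_score(
    lesion_params("mass", 1, visibility = 0.5, layout = lay)), 0.5)
  expect_equal(derive_guideline_score(
    lesion_params("mass", 1, visibility = 0, layout = lay)), 0.0)
  expect_error(lesion_params("blob", 1), "arg")
})

test_that("longest continuous run matches a brute-force segment trace", {
  lay <- test_layout()
  cases <- list(
    list(vis = 1, breaks = 0.5), list(vis = 1, breaks = c(0.3, 0.7)),
    list(vis = 0.8, breaks = 0.2), list(vis = 0.6, breaks = numeric(0)),
    list(vis = 1, breaks = c(0.2, 0.4, 0.6, 0.8)),
    list(vis = 0.55, breaks = 0.5))
  for (cs in cases) {
    p <- lesion_params("fiber", 3, visibility = cs$vis,
                       break_positions = cs$breaks, layout = lay)
    gap <- lay$gap_frac(p$size)
    expect_equal(longest_visible_run(p, lay),
                 brute_force_longest_run(cs$vis, cs$breaks, gap),
                 tolerance = 1e-3)
  }
  # a central break leaves no run above half: neither 1.0 nor 0.5
  p <- lesion_params("fiber", 1, visibility = 1, break_positions = 0.5,
                     layout = lay)
  expect_lte(longest_visible_run(p, lay), 0.5)
  expect_true(is.na(derive_guideline_score(p)))
  expect_equal(derive_guideline_score(
    p, scoring_config(fiber_short_na = FALSE)), 0.0)
})

test_that("rendering is deterministic and photometric inversion is exact", {
  lay <- test_layout()
  spec <- phantom_spec(seed = 123, noise_sigma = 0.015)
  r1 <- render_phantom(spec, lay)
  r2 <- render_phantom(spec, lay)
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$truth$scores, r2$truth$scores)
  spec1 <- phantom_spec(seed = 123, noise_sigma = 0.015,
                        photometric = "monochrome1")
  r3 <- render_phantom(spec1, lay)
  maxval <- 2^spec$bit_depth - 1
  expect_identical(r3$image$pixels, maxval - r1$image$pixels)
})

test_that("fully visible noiseless phantom scores all 1.0 and qualifies", {
  nom <- nominal_phantom()
  expect_equal(nom$render$truth$scores, rep(1, 16))
  expect_true(nom$render$truth$qualified)
})

test_that("ground truth scores are consistent with the parameter rules", {
  lay <- test_layout()
  ds <- sample_dataset(6, seed = 31, layout = lay)
  specs <- sample_specs(6, seed = 31, layout = lay)
  for (i in seq_along(ds)) {
    expected <- vapply(specs[[i]]$lesions, derive_guideline_score, 0,
                       layout = lay)
    expect_identical(ds[[i]]$truth$scores, expected)
    expect_identical(ds[[i]]$truth$qualified,
                     qualify_phantom(expected, lay)$qualified)
  }
})

test_that("noiseless lesions rise strictly above their local background", {
  lay <- test_layout()
  spec <- phantom_spec(noise_sigma = 0, seed = 9, artifacts = FALSE)
  tiles <- split_grid(render_standardized(spec, lay), lay)
  for (i in 1:16) {
    g <- lesion_geometry(lay, i)
    px <- tiles[[i]]$pixels
    bg <- median(px)
    peak <- max(vapply(g$probe_points, function(p)
      bilinear_at(px, p[1], p[2]), 0))
    expect_gt(peak, bg)
  }
})

test_that("a sweep of rendered fiber fractions scores monotonically", {
  lay <- test_layout()
  vis <- seq(0.1, 1, by = 0.1)
  sc <- vapply(vis, function(v)
    derive_guideline_score(lesion_params("fiber", 2, visibility = v,
                                         layout = lay),
                           scoring_config(fiber_short_na = FALSE)), 0)
  expect_true(all(diff(sc) >= 0))
  expect_equal(sc[length(sc)], 1.0)
})

test_that("fibers with only the largest partly visible score (0.5,0,0,0,0,0)", {
  lay <- test_layout()
  lesions <- full_visibility_lesions(lay)
  lesions[[1]] <- lesion_params("fiber", 1, visibility = 0.6, layout = lay)
  for (i in 2:6)
    lesions[[i]] <- lesion_params("fiber", lay$cells$rank[i], visibility = 0,
                                  layout = lay)
  spec <- phantom_spec(lesions, noise_sigma = 0, seed = 1)
  r <- render_phantom(spec, lay)
  expect_equal(r$truth$scores[1:6], c(0.5, 0, 0, 0, 0, 0))
})

test_that("dataset sampling is seeded and label frequencies are controllable", {
  lay <- test_layout()
  d1 <- sample_dataset(4, seed = 77, layout = lay)
  d2 <- sample_dataset(4, seed = 77, layout = lay)
  expect_identical(lapply(d1, function(x) x$image$pixels),
                   lapply(d2, function(x) x$image$pixels))
  # all-visible distribution: every phantom qualifies
  all_vis <- sampling_distribution(p_full = 1, p_absent = 0)
  dv <- sample_specs(10, all_vis, seed = 5, layout = lay)
  qs <- vapply(dv, function(s)
    qualify_phantom(vapply(s$lesions, derive_guideline_score, 0,
                           layout = lay), lay)$qualified, TRUE)
  expect_true(all(qs))
  # per-lesion full-visibility probability drives the 1.0-score fraction:
  # fibers score 1.0 exactly when drawn fully visible, so the observed
  # fraction over 500 phantoms x 6 fibers is binomial around p_full
  specs <- sample_specs(500, sampling_distribution(p_full = 0.8), seed = 6,
                        layout = lay)
  fib <- unlist(lapply(specs, function(s)
    vapply(s$lesions[1:6], derive_guideline_score, 0, layout = lay)))
  frac <- mean(!is.na(fib) & fib == 1)
  se <- sqrt(0.8 * 0.2 / length(fib))
  expect_lt(abs(frac - 0.8), 4 * se + 0.005)
  expect_error(sample_specs(0), "n must be")
  expect_error(sampling_distribution(fiber_partial = c(0.5)), "range")
})

test_that("canvas too small for the phantom is rejected", {
  expect_error(phantom_spec(canvas_size = c(100L, 100L)), "canvas too small")
  expect_error(lesion_params("fiber", 9), "rank")
  expect_error(lesion_params("mass", 1, break_positions = 0.4), "break")
  expect_error(lesion_params("specks", 1, visibility = c(1, 1)), "length 6")
})
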