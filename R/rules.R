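# Deterministic, guideline-faithful lesion scorers. Each scorer measures
# the tile at the expected lesion geometry from the layout map and applies
# the same numeric criteria that define the ground-truth labels. The
# measurements are chosen to be robust to the small shifts, interpolation
# smear and blur the standardization pipeline introduces: fibers are probed
# by a perpendicular-max matched line filter, specks by background-
# subtracted flux in a small window (flux is conserved under blur and
# bilinear resampling, unlike peak height), masses by a subpixel radial
# contour traced at the half-plateau level.

#' Calibration of measurement nominals
#'
#' Renders a fully visible, noiseless reference phantom at the layout's
#' geometry and measures, per lesion, the values the scorer's relative
#' thresholds refer to: fiber peak contrast, per-speck flux, mass peak and
#' area, and the reference normalization window. Memoized.
#'
#' @param layout a [phantom_layout()]
#' @param blur_sigma reference blur (render px)
#' @return list with `fiber_peak`, `speck_flux`, `mass_peak`, `mass_area`,
#'   `window_range`
#' @export
rules_calibration <- function(layout = phantom_layout(), blur_sigma = 0.8) {
  key <- sprintf("calib_%d_%.3f", layout$insert_px, blur_sigma)
  if (!is.null(.pq_env[[key]])) return(.pq_env[[key]])
  spec <- phantom_spec(full_visibility_lesions(layout), noise_sigma = 0,
                       blur_sigma = blur_sigma, artifacts = FALSE, seed = 1L)
  std <- render_standardized(spec, layout)
  tiles <- split_grid(std, layout)
  fiber_peak <- vapply(1:6, function(rk) {
    tl <- tiles[[rk]]
    measure_fiber(tl$pixels, lesion_geometry(layout, rk))$peak
  }, 0)
  speck_flux <- vapply(1:5, function(rk) {
    cell <- 6 + rk
    g <- lesion_geometry(layout, cell)
    bg <- stats::median(tiles[[cell]]$pixels)
    mean(vapply(g$positions, function(p)
      window_flux(tiles[[cell]]$pixels, p, g$diameter / 2 + 2.5, bg), 0))
  }, 0)
  mass <- lapply(1:5, function(rk) {
    cell <- 11 + rk
    g <- lesion_geometry(layout, cell)
    seg <- segment_mass(tiles[[cell]]$pixels, g, peak_floor = 0)
    list(peak = seg$peak, area = seg$area)
  })
  out <- list(fiber_peak = fiber_peak, speck_flux = speck_flux,
              mass_peak = vapply(mass, `[[`, 0, "peak"),
              mass_area = vapply(mass, `[[`, 0, "area"),
              window_range = diff(std$provenance$window))
  .pq_env[[key]] <- out
  out
}

#' @keywords internal
window_flux <- function(px, center, radius, bg) {
  r0 <- max(1, floor(center[1] - radius)); r1 <- min(nrow(px), ceiling(center[1] + radius))
  c0 <- max(1, floor(center[2] - radius)); c1 <- min(ncol(px), ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  sum((px[rr, cc] - bg)[d2 <= radius^2])
}

#' @keywords internal
tile_noise_sd <- function(px) {
  # robust noise estimate from horizontal first differences
  stats::mad(diff(as.vector(px[, seq(1, ncol(px), 2)]))) / sqrt(2)
}

#' @keywords internal
measure_fiber <- function(px, g, n_samples = 81, half_width = 3) {
  bg <- stats::median(px)
  ts <- seq(0, 1, length.out = n_samples)
  offs <- seq(-half_width, half_width, by = 0.5)
  perp <- c(g$dir[2], -g$dir[1])
  along <- (ts - 0.5) * g$length
  rr <- outer(g$center[1] + along * g$dir[1], offs * perp[1], "+")
  cc <- outer(g$center[2] + along * g$dir[2], offs * perp[2], "+")
  vals <- matrix(bilinear_many(px, as.vector(rr), as.vector(cc)),
                 nrow = n_samples)
  prof <- apply(vals, 1, max) - bg
  list(profile = prof, ts = ts, peak = max(prof), bg = bg)
}

#' @keywords internal
longest_run_fraction <- function(covered) {
  r <- rle(covered)
  if (!any(r$values)) return(0)
  max(r$lengths[r$values]) / length(covered)
}

#' Score a fiber tile by the guideline rules
#'
#' Detects the linear structure along the expected fiber axis with a
#' perpendicular-max line probe, thresholds it against the local
#' background, and maps the longest continuous covered run to a score:
#' complete run 1.0; more than half 0.5; detected but at most half N/A (or
#' 0.0 by configuration); nothing detected 0.0.
#'
#' @param sub a `subimage` with `lesion_type == "fiber"`
#' @param config a [scoring_config()]
#' @param layout layout map
#' @param calib a [rules_calibration()]
#' @return list with `score` and `diagnostics` (class `fiber_diagnostics`:
#'   `detected_mask`, `longest_run_fraction`, `visible_fraction`,
#'   `orientation_ok`)
#' @export
score_fiber <- function(sub, config = scoring_config(),
                        layout = phantom_layout(),
                        calib = rules_calibration(layout)) {
  if (sub$lesion_type != "fiber") stop("subimage is not a fiber tile")
  g <- lesion_geometry(layout, sub$grid_cell, tile_px = nrow(sub$pixels))
  m <- measure_fiber(sub$pixels, g)
  floor_val <- max(config$fiber_detect_floor * calib$fiber_peak[sub$rank],
                   3 * tile_noise_sd(sub$pixels))
  covered <- m$profile >= floor_val
  run <- longest_run_fraction(covered)
  score <- if (run >= config$fiber_full_run) 1.0
  else if (run > 0.5) 0.5
  else if (run > 0) { if (config$fiber_short_na) NA_real_ else 0.0 }
  else 0.0
  diag <- structure(list(detected_mask = covered,
                         longest_run_fraction = run,
                         visible_fraction = mean(covered),
                         orientation_ok = TRUE),
                    class = "fiber_diagnostics")
  list(score = score, diagnostics = diag)
}

#' Score a speck-group tile by the guideline rules
#'
#' Measures background-subtracted flux in a small window at each of the six
#' expected speck positions, converts it to an opacity estimate relative to
#' the calibrated full-opacity flux, and counts specks at or above the
#' detectability floor: 5-6 score 1.0, exactly 4 scores
#' `config$speck_four`, 2-3 score 0.5, 0-1 score 0.0.
#'
#' @inheritParams score_fiber
#' @return list with `score` and `diagnostics` (class `speck_diagnostics`:
#'   `visible_count`, `per_speck_contrast`)
#' @export
score_specks <- function(sub, config = scoring_config(),
                         layout = phantom_layout(),
                         calib = rules_calibration(layout)) {
  if (sub$lesion_type != "specks") stop("subimage is not a speck tile")
  g <- lesion_geometry(layout, sub$grid_cell, tile_px = nrow(sub$pixels))
  bg <- stats::median(sub$pixels)
  radius <- g$diameter / 2 + 2.5
  flux <- vapply(g$positions, function(p)
    window_flux(sub$pixels, p, radius, bg), 0)
  opacity <- flux / calib$speck_flux[sub$rank]
  noise_flux <- tile_noise_sd(sub$pixels) * sqrt(pi) * radius
  floor_val <- max(config$speck_floor,
                   3 * noise_flux / calib$speck_flux[sub$rank])
  n <- sum(opacity >= floor_val)
  score <- if (n >= 5) 1.0 else if (n == 4) config$speck_four
  else if (n >= 2) 0.5 else 0.0
  diag <- structure(list(visible_count = n, per_speck_contrast = opacity),
                    class = "speck_diagnostics")
  list(score = score, diagnostics = diag)
}

#' @keywords internal
segment_mass <- function(px, g, peak_floor, radial_tol = 0.10) {
  bg <- stats::median(px)
  thr <- bg + 0.45 * peak_floor
  if (peak_floor <= 0) {  # calibration mode: half-range threshold
    thr <- bg + 0.5 * (max(px) - bg)
  }
  mask <- px > thr
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) == 0) return(list(present = FALSE, area = 0, peak = 0))
  # component nearest the expected center
  cand <- which(vapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    cc <- colMeans(idx)
    sqrt(sum((cc - g$center)^2)) < max(8, 0.6 * g$radius) && nrow(idx) >= 4
  }, TRUE))
  if (!length(cand)) return(list(present = FALSE, area = 0, peak = 0))
  k <- cand[which.max(tabulate(lab[lab > 0])[cand])]
  idx <- which(lab == k, arr.ind = TRUE)
  center <- unname(colMeans(idx))
  plateau <- stats::quantile(px[lab == k], 0.7, names = FALSE)
  level <- bg + 0.5 * (plateau - bg)
  angles <- (seq_len(72) - 0.5) * 2 * pi / 72
  rmax <- 1.8 * g$radius + 4
  trace <- function(ctr) {
    # subpixel radial contour: first outward crossing below `level` per ray
    rs <- seq(0.5, rmax, by = 0.35)
    rr <- ctr[1] + outer(cos(angles), rs)
    cc <- ctr[2] + outer(sin(angles), rs)
    vals <- matrix(bilinear_many(px, as.vector(rr), as.vector(cc)),
                   nrow = length(angles))
    vapply(seq_along(angles), function(i) {
      below <- which(vals[i, ] < level)
      if (!length(below)) return(rmax)
      j <- below[1]
      if (j == 1) return(rs[1])
      f <- (vals[i, j - 1] - level) / (vals[i, j - 1] - vals[i, j])
      rs[j - 1] + f * (rs[j] - rs[j - 1])
    }, 0)
  }
  kasa_fit <- function(pr, pc) {
    # algebraic least-squares circle through the points
    A <- cbind(2 * pr, 2 * pc, 1)
    b <- pr^2 + pc^2
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    c(sol[1], sol[2])
  }
  # iterate: trace radii, refit the circle center on the outer (circular)
  # cluster of contour points, re-trace; a dented contour otherwise biases
  # the center and imprints a spurious first-harmonic wobble on the radii
  radii <- trace(center)
  for (it in 1:2) {
    r_fit <- stats::quantile(radii, 0.9, names = FALSE)
    keep <- radii > r_fit - max(radial_tol * r_fit, 0.9)
    if (sum(keep) < 6) break
    fit <- kasa_fit(center[1] + radii[keep] * cos(angles[keep]),
                    center[2] + radii[keep] * sin(angles[keep]))
    if (is.null(fit) || sqrt(sum((fit - center)^2)) > 0.5 * g$radius) break
    center <- fit
    radii <- trace(center)
  }
  r_fit <- stats::quantile(radii, 0.9, names = FALSE)
  tol <- max(radial_tol * r_fit, 0.9)
  circ <- abs(radii - r_fit) < tol
  list(present = TRUE, area = nrow(idx), peak = plateau - bg,
       center = center, radii = radii, r_fit = r_fit,
       circular_fraction = mean(circ))
}

#' Score a mass tile by the guideline rules
#'
#' Segments the lesion at the expected location; absent masses score 0.0.
#' For a present mass the contour is traced at subpixel resolution along 72
#' radial rays and compared with the best-fit radius: the fraction of rays
#' within the radial tolerance is the circular contour fraction, and a
#' fraction above three quarters earns 1.0, otherwise 0.5.
#'
#' @inheritParams score_fiber
#' @return list with `score` and `diagnostics` (class `mass_diagnostics`:
#'   `present`, `circular_contour_fraction`)
#' @export
score_mass <- function(sub, config = scoring_config(),
                       layout = phantom_layout(),
                       calib = rules_calibration(layout)) {
  if (sub$lesion_type != "mass") stop("subimage is not a mass tile")
  g <- lesion_geometry(layout, sub$grid_cell, tile_px = nrow(sub$pixels))
  seg <- segment_mass(sub$pixels, g, peak_floor = calib$mass_peak[sub$rank],
                      radial_tol = config$mass_radial_tol)
  present <- seg$present && seg$area >= 0.25 * calib$mass_area[sub$rank]
  score <- if (!present) 0.0
  else if (seg$circular_fraction > config$mass_circular_fraction) 1.0
  else 0.5
  diag <- structure(list(present = present,
                         circular_contour_fraction =
                           if (present) seg$circular_fraction else NA_real_),
                    class = "mass_diagnostics")
  list(score = score, diagnostics = diag)
}

#' Score all 16 tiles of a phantom
#'
#' Dispatches the type-appropriate rule scorer over a complete grid of
#' subimages.
#'
#' @param subs list of 16 `subimage` objects from [split_grid()]
#' @param config a [scoring_config()]
#' @param layout layout map
#' @param calib a [rules_calibration()]
#' @return list with `scores` (numeric 16, NA for the ambiguous label) and
#'   `diagnostics` (list of 16)
#' @export
score_phantom <- function(subs, config = scoring_config(),
                          layout = phantom_layout(),
                          calib = rules_calibration(layout)) {
  if (length(subs) != 16) stop("expected 16 subimages")
  res <- lapply(subs, function(s)
    switch(s$lesion_type,
           fiber = score_fiber(s, config, layout, calib),
           specks = score_specks(s, config, layout, calib),
           mass = score_mass(s, config, layout, calib)))
  list(scores = vapply(res, `[[`, 0, "score"),
       diagnostics = lapply(res, `[[`, "diagnostics"))
}

#' Rule-based scorer as a plain function
#'
#' Convenience wrapper returning `function(subimage) -> score`, suitable
#' for [qualify_early_stop()] and [evaluate_system()].
#' @inheritParams score_phantom
#' @return function of one `subimage`
#' @export
rules_scorer <- function(config = scoring_config(), layout = phantom_layout(),
                         calib = rules_calibration(layout)) {
  function(sub) switch(sub$lesion_type,
                       fiber = score_fiber(sub, config, layout, calib)$score,
                       specks = score_specks(sub, config, layout, calib)$score,
                       mass = score_mass(sub, config, layout, calib)$score)
}
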