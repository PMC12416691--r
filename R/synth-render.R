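# Scene composition constants (render px): the phantom body is a 300x280
# acrylic block; the 240x240 lesion insert sits 20 px below its top edge,
# horizontally centered, leaving a 40 px strip at the bottom for the disc
# marker and text-like labels.
.body_h <- 300; .body_w <- 280
.insert_off <- c(20, 20)  # insert offset (rows, cols) inside the body
.air_level <- 0.02

#' @keywords internal
add_soft_disc <- function(m, center, radius, value) {
  r0 <- max(1, floor(center[1] - radius - 2)); r1 <- min(nrow(m), ceiling(center[1] + radius + 2))
  c0 <- max(1, floor(center[2] - radius - 2)); c1 <- min(ncol(m), ceiling(center[2] + radius + 2))
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - center[1])^2, (cc - center[2])^2, "+"))
  m[rr, cc] <- m[rr, cc] + value * clamp01(radius - d + 0.5)
  m
}

#' @keywords internal
add_fiber_segment <- function(m, center, dir, len, width, value, t0, t1) {
  # soft-edged rectangle along the axis between fractional positions t0, t1
  half <- len / 2
  p0 <- center + (t0 - 0.5) * len * dir
  p1 <- center + (t1 - 0.5) * len * dir
  lo <- pmin(p0, p1) - width - 2; hi <- pmax(p0, p1) + width + 2
  rr <- max(1, floor(lo[1])):min(nrow(m), ceiling(hi[1]))
  cc <- max(1, floor(lo[2])):min(ncol(m), ceiling(hi[2]))
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  along <- dr * dir[1] + dc * dir[2]          # signed distance along axis
  perp <- abs(dr * dir[2] - dc * dir[1])      # distance off axis
  a0 <- (t0 - 0.5) * len; a1 <- (t1 - 0.5) * len
  cov <- clamp01(width / 2 - perp + 0.5) *
    clamp01(along - a0 + 0.5) * clamp01(a1 - along + 0.5)
  m[rr, cc] <- m[rr, cc] + value * cov
  m
}

#' @keywords internal
add_mass_shape <- function(m, center, radius, value, circ_fraction, dent_factor) {
  if (circ_fraction <= 0) return(m)
  pad <- radius + 3
  rr <- max(1, floor(center[1] - pad)):min(nrow(m), ceiling(center[1] + pad))
  cc <- max(1, floor(center[2] - pad)):min(ncol(m), ceiling(center[2] + pad))
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)  # (-pi, pi]
  # circular arc spans angles [-pi, -pi + 2*pi*fraction); remainder dented
  frac <- (theta + pi) / (2 * pi)
  redge <- ifelse(frac < circ_fraction, radius, radius * dent_factor)
  m[rr, cc] <- m[rr, cc] + value * clamp01(redge - d + 0.5)
  m
}

#' Render the lesion insert of a phantom (no blur/noise)
#'
#' @param spec a [phantom_spec()]
#' @param layout layout map
#' @return square matrix of scene intensities, insert background included
#' @export
render_insert <- function(spec, layout = phantom_layout()) {
  n <- layout$insert_px
  m <- matrix(spec$insert_level, n, n)
  for (p in spec$lesions) {
    ctr <- cell_center(layout, p$cell)
    if (p$lesion_type == "fiber") {
      iv <- fiber_intervals(p$visibility, p$break_positions,
                            layout$gap_frac(p$size))
      for (k in seq_len(nrow(iv)))
        m <- add_fiber_segment(m, ctr, layout$fiber_dir, p$size,
                               layout$fiber_width, p$contrast,
                               iv[k, 1], iv[k, 2])
    } else if (p$lesion_type == "specks") {
      off <- speck_offsets(layout)
      for (j in 1:6)
        if (p$visibility[j] > 0)
          m <- add_soft_disc(m, ctr + off[j, ], p$size / 2,
                             p$contrast * p$visibility[j])
    } else {
      m <- add_mass_shape(m, ctr, p$size / 2, p$contrast,
                          p$visibility, layout$mass_dent_factor)
    }
  }
  m
}

#' Render a synthetic phantom radiograph with ground truth
#'
#' Composes the phantom body, lesion insert and optional artifacts on an
#' air background, applies the Gaussian point-spread blur, the requested
#' orientation (fine rotation plus quarter turns) and translation, adds
#' seeded detector noise, quantizes to the stored bit depth and applies the
#' photometric polarity. Deterministic for a fixed spec (seed included).
#'
#' @param spec a [phantom_spec()]
#' @param layout layout map
#' @return list with elements `image` (a [raw_image()]), `truth` (class
#'   `ground_truth`: 16 scores plus the qualification verdict) and `info`
#'   (true insert box and lesion centers in canvas coordinates before
#'   rotation, for validation against the preprocessing pipeline)
#' @export
render_phantom <- function(spec, layout = phantom_layout()) {
  cs <- spec$canvas_size
  scene <- matrix(.air_level, cs[1], cs[2])
  # body bottom-center with 10 px bottom margin, plus translation
  top <- cs[1] - 10 - .body_h + spec$translation[1]
  left <- floor((cs[2] - .body_w) / 2) + spec$translation[2]
  if (top < 1 || left < 1 || top + .body_h - 1 > cs[1] ||
      left + .body_w - 1 > cs[2])
    stop("canvas too small for requested translation")
  scene[top:(top + .body_h - 1), left:(left + .body_w - 1)] <- spec$background_level
  it <- top + .insert_off[1]; il <- left + .insert_off[2]
  ins <- render_insert(spec, layout)
  n <- layout$insert_px
  scene[it:(it + n - 1), il:(il + n - 1)] <- ins
  if (isTRUE(spec$artifacts)) {
    strip_r <- it + n + 18
    scene <- add_soft_disc(scene, c(strip_r, il + 30), 9, 0.5)
    for (k in 0:3)  # text-like tick marks
      scene[(strip_r - 6):(strip_r + 6), (il + 90 + 14 * k):(il + 96 + 14 * k)] <-
        spec$background_level + 0.4
  }
  scene <- blur_matrix(scene, spec$blur_sigma)
  scene <- rotate_matrix(scene, spec$fine, fill = .air_level)
  scene <- rot_quarter(scene, spec$coarse_quarters)
  if (spec$noise_sigma > 0)
    scene <- scene + with_seed(spec$seed,
      matrix(stats::rnorm(length(scene), 0, spec$noise_sigma),
             nrow(scene), ncol(scene)))
  maxval <- 2^spec$bit_depth - 1
  px <- round(clamp01(scene) * maxval)
  if (spec$photometric == "monochrome1") px <- maxval - px
  scores <- vapply(spec$lesions, derive_guideline_score, 0,
                   layout = layout)
  truth <- structure(list(
    scores = scores,
    qualified = qualify_phantom(scores, layout = layout)$qualified
  ), class = "ground_truth")
  info <- list(
    insert_box = c(it, il, it + n - 1, il + n - 1),
    lesion_centers = t(vapply(spec$lesions, function(p)
      cell_center(layout, p$cell) + c(it, il) - 1, c(0, 0))),
    rotation = spec$rotation, translation = spec$translation
  )
  list(image = raw_image(px, spec$photometric, spec$bit_depth),
       truth = truth, info = info)
}

#' Fast path: standardized image straight from the generator
#'
#' Renders only the lesion insert, applies blur and seeded noise, then the
#' same rhombus-window normalization and 224 x 224 resize the preprocessing
#' pipeline performs. Used for calibration and for generating training
#' tiles at scale without the localization stages.
#'
#' @param spec a [phantom_spec()]
#' @param layout layout map
#' @return a `standardized_image`
#' @export
render_standardized <- function(spec, layout = phantom_layout()) {
  ins <- render_insert(spec, layout)
  # pad with body-level margin before blurring so the insert border carries
  # the same blurred transition the pipeline's crop has, then crop back
  pad <- 8L; n <- layout$insert_px
  padded <- matrix(spec$background_level, n + 2 * pad, n + 2 * pad)
  padded[(pad + 1):(pad + n), (pad + 1):(pad + n)] <- ins
  ins <- blur_matrix(padded, spec$blur_sigma)[(pad + 1):(pad + n),
                                              (pad + 1):(pad + n)]
  if (spec$noise_sigma > 0)
    ins <- ins + with_seed(spec$seed,
      matrix(stats::rnorm(length(ins), 0, spec$noise_sigma),
             nrow(ins), ncol(ins)))
  normalize_and_resize(ins)
}

#' Default per-parameter sampling distribution for synthetic datasets
#'
#' Each lesion is independently fully visible with probability `p_full`,
#' absent with probability `p_absent`, and partially visible otherwise
#' (fiber: reduced length and/or a break; specks: i.i.d. uniform per-speck
#' opacities; mass: partial circular contour). Acquisition nuisances
#' (noise, blur, orientation, translation, polarity) are sampled per
#' phantom. The defaults imitate the class imbalance of real submissions,
#' where roughly 80 percent of lesions earn a full point.
#'
#' @param p_full probability a lesion is rendered fully visible
#' @param p_absent probability a lesion is not rendered at all
#' @param fiber_partial range of partial fiber visible fractions
#' @param mass_partial range of partial mass contour fractions
#' @param fiber_break_prob probability a partial fiber carries one break
#' @param noise range of per-phantom noise sigma
#' @param blur range of per-phantom blur sigma
#' @param fine_rotation range of fine rotation angles (degrees)
#' @param coarse_probs probabilities of 0/90/180/270 degree orientations
#' @param translation_max maximum |offset| in rows and cols (px)
#' @param mono1_prob probability of monochrome1 polarity
#' @param artifacts render disc/text artifacts
#' @return list of class `sampling_distribution`
#' @export
sampling_distribution <- function(p_full = 0.8, p_absent = 0.05,
                                  fiber_partial = c(0.20, 0.97),
                                  mass_partial = c(0.20, 0.95),
                                  fiber_break_prob = 0.5,
                                  noise = c(0.005, 0.02),
                                  blur = c(0.6, 1.0),
                                  fine_rotation = c(-3, 3),
                                  coarse_probs = c(0.85, 0.05, 0.05, 0.05),
                                  translation_max = 8,
                                  mono1_prob = 0.1,
                                  artifacts = TRUE) {
  if (p_full + p_absent > 1) stop("p_full + p_absent must not exceed 1")
  if (diff(range(fiber_partial)) < 0 || diff(range(mass_partial)) < 0 ||
      length(fiber_partial) != 2 || length(mass_partial) != 2)
    stop("empty partial-visibility range")
  structure(as.list(environment()), class = "sampling_distribution")
}

#' @keywords internal
sample_lesion <- function(type, rank, dist, layout) {
  u <- stats::runif(1)
  if (u < dist$p_full) {
    vis <- 1; brk <- numeric(0)
  } else if (u < dist$p_full + dist$p_absent) {
    vis <- 0; brk <- numeric(0)
  } else {
    brk <- numeric(0)
    if (type == "fiber") {
      vis <- stats::runif(1, dist$fiber_partial[1], dist$fiber_partial[2])
      if (stats::runif(1) < dist$fiber_break_prob)
        brk <- stats::runif(1, 0.15, 0.85)
    } else if (type == "specks") {
      vis <- stats::runif(6)
    } else {
      vis <- stats::runif(1, dist$mass_partial[1], dist$mass_partial[2])
    }
  }
  if (type == "specks" && length(vis) == 1) vis <- rep(vis, 6)
  lesion_params(type, rank, visibility = vis, break_positions = brk,
                layout = layout)
}

#' Sample phantom specifications (no rendering)
#'
#' @param n number of phantoms (>= 1)
#' @param dist a [sampling_distribution()]
#' @param seed RNG seed; the i-th spec also receives a derived render seed
#' @param layout layout map
#' @param ... overrides passed to every [phantom_spec()] (e.g.
#'   `noise_sigma = 0` for noiseless renders)
#' @return list of [phantom_spec()]
#' @export
sample_specs <- function(n, dist = sampling_distribution(), seed = 1L,
                         layout = phantom_layout(), ...) {
  if (n < 1) stop("n must be >= 1")
  over <- list(...)
  with_seed(seed, lapply(seq_len(n), function(i) {
    lesions <- lapply(1:16, function(cl) {
      row <- layout$cells[cl, ]
      sample_lesion(row$lesion_type, row$rank, dist, layout)
    })
    args <- list(
      lesions = lesions,
      noise_sigma = stats::runif(1, dist$noise[1], dist$noise[2]),
      blur_sigma = stats::runif(1, dist$blur[1], dist$blur[2]),
      rotation = 90 * (sample.int(4, 1, prob = dist$coarse_probs) - 1) +
        stats::runif(1, dist$fine_rotation[1], dist$fine_rotation[2]),
      translation = sample(seq(-dist$translation_max, dist$translation_max), 2,
                           replace = TRUE),
      photometric = if (stats::runif(1) < dist$mono1_prob) "monochrome1"
                    else "monochrome2",
      artifacts = dist$artifacts,
      seed = sample.int(2^30, 1)
    )
    args[names(over)] <- over
    do.call(phantom_spec, args)
  }))
}

#' Sample a rendered synthetic dataset with ground truth
#'
#' @inheritParams sample_specs
#' @return list of `n` elements, each as returned by [render_phantom()]
#' @export
sample_dataset <- function(n, dist = sampling_distribution(), seed = 1L,
                           layout = phantom_layout(), ...) {
  specs <- sample_specs(n, dist, seed, layout, ...)
  lapply(specs, render_phantom, layout = layout)
}
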