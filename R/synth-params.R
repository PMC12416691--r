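#' Generative parameters of one lesion
#'
#' @param lesion_type one of "fiber", "specks", "mass"
#' @param rank 1-based size rank within the family (1 = largest); 1..6 for
#'   fibers, 1..5 for specks and masses
#' @param visibility for a fiber, the fraction of its length rendered; for
#'   a speck group, a length-6 vector of per-speck opacities in \[0,1\]; for
#'   a mass, the fraction of its contour rendered circular (0 = absent)
#' @param break_positions fractional positions in (0,1) along a fiber where
#'   gaps are rendered; must be empty for other lesion types
#' @param layout layout map supplying nominal size and contrast
#' @return object of class `lesion_params`
#' @export
lesion_params <- function(lesion_type, rank, visibility = 1,
                          break_positions = numeric(0),
                          layout = phantom_layout()) {
  lesion_type <- match.arg(lesion_type, c("fiber", "specks", "mass"))
  max_rank <- if (lesion_type == "fiber") 6L else 5L
  if (!is.numeric(rank) || length(rank) != 1 || rank < 1 || rank > max_rank)
    stop("invalid rank for lesion_type '", lesion_type, "'")
  if (lesion_type == "specks") {
    if (length(visibility) == 1) visibility <- rep(visibility, 6)
    if (length(visibility) != 6) stop("specks visibility must have length 6")
  } else if (length(visibility) != 1) {
    stop("visibility must be a scalar for ", lesion_type)
  }
  if (any(visibility < 0 | visibility > 1)) stop("visibility must lie in [0,1]")
  if (length(break_positions) && lesion_type != "fiber")
    stop("break_positions only apply to fibers")
  if (any(break_positions <= 0 | break_positions >= 1))
    stop("break_positions must lie in (0,1)")
  row <- layout$cells[layout$cells$lesion_type == lesion_type &
                        layout$cells$rank == rank, ]
  structure(list(
    lesion_type = lesion_type, rank = as.integer(rank),
    size = row$size, contrast = row$contrast,
    visibility = visibility,
    break_positions = sort(as.numeric(break_positions)),
    cell = row$cell
  ), class = "lesion_params")
}

#' The 16 lesions of a fully visible phantom
#' @param layout layout map
#' @return list of 16 [lesion_params()] in grid-cell order
#' @export
full_visibility_lesions <- function(layout = phantom_layout()) {
  lapply(1:16, function(i) {
    row <- layout$cells[i, ]
    lesion_params(row$lesion_type, row$rank, visibility = 1, layout = layout)
  })
}

#' Generative parameters of one synthetic phantom radiograph
#'
#' @param lesions list of 16 [lesion_params()] in grid-cell order (6 fibers,
#'   5 speck groups, 5 masses)
#' @param background_level base intensity of the phantom body (scene units)
#' @param insert_level intensity of the lesion insert (gel) region
#' @param noise_sigma Gaussian noise standard deviation (scene units)
#' @param blur_sigma Gaussian point-spread sigma in render pixels
#' @param artifacts render the disc marker and text-like labels on the
#'   phantom body outside the insert
#' @param photometric "monochrome2" (default; bright phantom on dark
#'   background) or "monochrome1" (inverted polarity)
#' @param rotation rotation applied at render time, in degrees; decomposed
#'   into the nearest multiple of 90 plus a fine residual (|fine| <= 45)
#' @param translation integer (rows, cols) offset of the phantom from
#'   bottom-center
#' @param canvas_size (rows, cols) of the output image
#' @param bit_depth stored bit depth of the quantized image
#' @param seed RNG seed used for the noise field
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(lesions = full_visibility_lesions(),
                         background_level = 0.45, insert_level = 0.58,
                         noise_sigma = 0.01, blur_sigma = 0.8,
                         artifacts = TRUE, photometric = "monochrome2",
                         rotation = 0, translation = c(0L, 0L),
                         canvas_size = c(420L, 360L), bit_depth = 12L,
                         seed = 1L) {
  photometric <- match.arg(photometric, c("monochrome2", "monochrome1"))
  types <- vapply(lesions, function(l) l$lesion_type, "")
  if (length(lesions) != 16 || sum(types == "fiber") != 6 ||
      sum(types == "specks") != 5 || sum(types == "mass") != 5)
    stop("lesions must contain exactly 6 fibers, 5 speck groups and 5 masses")
  ord <- vapply(lesions, function(l) l$cell, 0L)
  if (!identical(sort(ord), 1:16)) stop("lesions must cover grid cells 1..16")
  lesions <- lesions[order(ord)]
  if (noise_sigma < 0 || blur_sigma < 0) stop("negative noise/blur sigma")
  coarse <- ((round(rotation / 90) %% 4) + 4) %% 4
  fine <- rotation - 90 * round(rotation / 90)
  # body 300x280 plus margins must fit the canvas in either orientation
  need <- 320 + 2 * max(abs(translation))
  if (any(canvas_size < need))
    stop("canvas too small to contain the rotated phantom")
  structure(list(
    lesions = lesions, background_level = background_level,
    insert_level = insert_level, noise_sigma = noise_sigma,
    blur_sigma = blur_sigma, artifacts = artifacts,
    photometric = photometric,
    rotation = rotation, coarse_quarters = as.integer(coarse), fine = fine,
    translation = as.integer(round(translation)),
    canvas_size = as.integer(canvas_size), bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Scoring configuration for guideline rules
#'
#' Numerical interpretation of the national guideline wording. `speck_four`
#' selects the score for exactly four distinctly visible specks (the
#' guideline awards 1.0 for "more than 4" and 0.5 for "2-3", leaving 4
#' undefined; the default follows the observed model behaviour of full
#' credit at 3-4 visible specks). `fiber_short_na` scores a fiber whose
#' longest continuous visible run is positive but at most half as N/A
#' rather than 0.0, mirroring the ambiguous-case label.
#'
#' @param speck_floor opacity fraction of nominal contrast above which a
#'   speck counts as distinctly visible
#' @param speck_four score assigned to exactly 4 visible specks (1.0 or 0.5)
#' @param fiber_short_na logical; N/A (TRUE) or 0.0 for short fibers
#' @param fiber_full_run measured longest-run fraction at or above which a
#'   detected fiber counts as complete
#' @param fiber_detect_floor fraction of nominal peak contrast required to
#'   call a fiber sample covered
#' @param mass_circular_fraction contour fraction strictly above which a
#'   mass scores 1.0
#' @param mass_radial_tol radial deviation (fraction of fitted radius)
#'   within which a contour bin counts as circular
#' @return list of class `scoring_config`
#' @export
scoring_config <- function(speck_floor = 0.3, speck_four = 1.0,
                           fiber_short_na = TRUE, fiber_full_run = 0.92,
                           fiber_detect_floor = 0.4,
                           mass_circular_fraction = 0.75,
                           mass_radial_tol = 0.10) {
  stopifnot(speck_four %in% c(1.0, 0.5))
  structure(list(speck_floor = speck_floor, speck_four = speck_four,
                 fiber_short_na = fiber_short_na,
                 fiber_full_run = fiber_full_run,
                 fiber_detect_floor = fiber_detect_floor,
                 mass_circular_fraction = mass_circular_fraction,
                 mass_radial_tol = mass_radial_tol),
            class = "scoring_config")
}
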