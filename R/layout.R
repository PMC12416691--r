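#' Phantom grid layout map
#'
#' The ACR-style accreditation phantom embeds 16 artificial lesions in a
#' 4x4 grid: six nylon fibers of decreasing diameter/length, five groups of
#' six simulated microcalcifications ("specks") of decreasing size, and five
#' low-contrast masses of decreasing diameter. The layout map fixes which
#' grid cell holds which lesion, the within-cell geometry (fiber axis, speck
#' cluster positions, mass center), and the nominal rendering sizes and
#' contrasts used both by the synthetic generator and by the rule-based
#' scorer as expected positions. Cells are numbered 1..16 in row-major
#' order; fibers occupy cells 1-6, speck groups 7-11, masses 12-16, rank 1
#' being the largest lesion of each family.
#'
#' All geometry is expressed in "insert pixels": the lesion-containing
#' insert is rendered at `insert_px` x `insert_px` (default 240, i.e. 60 px
#' grid cells, which maps exactly onto 56 px tiles after the 224 x 224
#' standardization resize). Contrasts are intensity deltas above the insert
#' background in normalized scene units.
#'
#' @param insert_px side length of the lesion insert in render pixels;
#'   must be a positive multiple of 4.
#' @return object of class `phantom_layout`: a list with a per-cell
#'   data frame (`cells`) and geometry constants.
#' @export
phantom_layout <- function(insert_px = 240) {
  stopifnot(insert_px > 0, insert_px %% 4 == 0)
  cell_px <- insert_px / 4
  cells <- data.frame(
    cell = 1:16,
    row = rep(1:4, each = 4),
    col = rep(1:4, times = 4),
    lesion_type = c(rep("fiber", 6), rep("specks", 5), rep("mass", 5)),
    rank = c(1:6, 1:5, 1:5),
    stringsAsFactors = FALSE
  )
  # nominal sizes (insert px) and contrasts (scene units above insert bg),
  # strictly decreasing in rank within each family
  fiber_len <- c(46, 42, 38, 34, 30, 26)
  fiber_contrast <- c(0.30, 0.27, 0.24, 0.22, 0.20, 0.18)
  speck_diam <- c(7.0, 6.0, 5.2, 4.4, 3.8)
  speck_contrast <- c(0.30, 0.28, 0.26, 0.24, 0.22)
  mass_radius <- c(16, 14, 12, 10.5, 9)
  mass_contrast <- c(0.20, 0.18, 0.16, 0.14, 0.12)
  cells$size <- c(fiber_len, speck_diam, 2 * mass_radius)
  cells$contrast <- c(fiber_contrast, speck_contrast, mass_contrast)
  structure(list(
    insert_px = insert_px,
    cell_px = cell_px,
    cells = cells,
    fiber_width = 3,
    # fiber axis: unit vector along the cell diagonal (row, col)
    fiber_dir = c(1, 1) / sqrt(2),
    speck_cluster_radius = 12 * cell_px / 60,
    speck_angles = (15 + 60 * (0:5)) * pi / 180,
    # radial factor of the non-circular (dented) part of a mass contour
    mass_dent_factor = 0.6,
    # fiber break gap width as fraction of fiber length (floor of 5 px)
    gap_frac = function(len) max(0.08, 5 / len)
  ), class = "phantom_layout")
}

#' Center of a grid cell in insert-pixel coordinates
#' @param layout a [phantom_layout()]
#' @param cell cell index 1..16
#' @return numeric (row, col), 1-based pixel coordinates
#' @export
cell_center <- function(layout, cell) {
  rc <- layout$cells[layout$cells$cell == cell, c("row", "col")]
  c((rc$row - 0.5) * layout$cell_px + 0.5, (rc$col - 0.5) * layout$cell_px + 0.5)
}

#' Speck positions of a group, relative to its cell center (insert px)
#' @keywords internal
speck_offsets <- function(layout) {
  r <- layout$speck_cluster_radius
  cbind(r * sin(layout$speck_angles), r * cos(layout$speck_angles))
}

.pq_env <- new.env(parent = emptyenv())

#' Expected lesion geometry inside a standardized tile
#'
#' Converts the layout-map geometry of one cell from insert pixels to tile
#' pixels (tiles are `tile_px` x `tile_px`, default 56): lesion type and
#' rank, tile-frame center, and the type-specific fields (fiber axis,
#' length and width; speck positions and diameter; mass radius).
#'
#' @param layout a [phantom_layout()]
#' @param cell grid cell 1..16
#' @param tile_px side length of the tile in pixels
#' @return list of geometry fields for the cell's lesion
#' @export
lesion_geometry <- function(layout, cell, tile_px = 56) {
  sc <- tile_px / layout$cell_px
  ctr <- c(tile_px / 2 + 0.5, tile_px / 2 + 0.5)
  row <- layout$cells[cell, ]
  g <- list(lesion_type = row$lesion_type, rank = row$rank, center = ctr)
  if (row$lesion_type == "fiber") {
    g$length <- row$size * sc
    g$dir <- layout$fiber_dir
    g$width <- layout$fiber_width * sc
    ts <- seq(0, 1, length.out = 21)
    g$probe_points <- lapply(ts, function(t)
      ctr + (t - 0.5) * g$length * g$dir)
  } else if (row$lesion_type == "specks") {
    off <- speck_offsets(layout) * sc
    g$positions <- lapply(1:6, function(j) ctr + off[j, ])
    g$diameter <- row$size * sc
    g$probe_points <- g$positions
  } else {
    g$radius <- row$size / 2 * sc
    g$probe_points <- list(ctr)
  }
  g
}
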