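#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate code with a temporary RNG seed, restoring the caller's state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Quarter-turn rotations of a matrix (clockwise)
#' @param m numeric matrix
#' @param k number of clockwise quarter turns (may be negative)
#' @keywords internal
rot_quarter <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Bilinear sample of a matrix at fractional (row, col)
#' @keywords internal
bilinear_at <- function(m, r, c) {
  r <- min(max(r, 1), nrow(m)); c <- min(max(c, 1), ncol(m))
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nrow(m)); c1 <- min(c0 + 1, ncol(m))
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r1, c0] * fr * (1 - fc) +
    m[r0, c1] * (1 - fr) * fc + m[r1, c1] * fr * fc
}

#' Vectorized bilinear sampling at fractional (row, col) positions
#' @keywords internal
bilinear_many <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

#' Gaussian blur of a plain matrix (EBImage backend)
#' @keywords internal
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  matrix(out, nrow(out), ncol(out))
}

#' Bilinear resize of a plain matrix (EBImage backend)
#' @keywords internal
resize_matrix <- function(m, nr, nc) {
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                            w = nr, h = nc))
  matrix(out, nrow(out), ncol(out))
}

#' Fine rotation of a plain matrix about its center (EBImage backend)
#' @keywords internal
rotate_matrix <- function(m, angle, fill = 0) {
  if (abs(angle) < 1e-12) return(m)
  out <- EBImage::imageData(EBImage::rotate(EBImage::Image(m), angle = angle,
                                            output.dim = dim(m),
                                            bg.col = fill))
  matrix(out, nrow(out), ncol(out))
}

#' Mask of the central rhombus (diamond with vertices at edge midpoints)
#' @keywords internal
rhombus_mask <- function(nr, nc) {
  r <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
  c <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
  outer(abs(r), abs(c), "+") <= 1
}
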