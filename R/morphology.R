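# Shift-based 3D morphology. All filters are separable-free brute force over
# the offsets of a discrete ball, which is fast at the radii used here (1-2).

# translate an array by an integer offset, filling exposed voxels
shift3 <- function(a, d, fill) {
  dims <- dim(a)
  if (all(d == 0L)) return(a)
  out <- array(fill, dims)
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (i in 1:3) {
    if (abs(d[i]) >= dims[i]) return(out)
    if (d[i] >= 0) {
      src[[i]] <- seq_len(dims[i] - d[i]); dst[[i]] <- seq.int(1 + d[i], dims[i])
    } else {
      src[[i]] <- seq.int(1 - d[i], dims[i]); dst[[i]] <- seq_len(dims[i] + d[i])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# integer offsets of a voxel ball of given radius (in voxels)
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

min_filter <- function(a, offsets, fill = Inf) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift3(a, offsets[i, ], fill)
    out <- if (is.null(out)) s else pmin(out, s)
  }
  out
}

max_filter <- function(a, offsets, fill = -Inf) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift3(a, offsets[i, ], fill)
    out <- if (is.null(out)) s else pmax(out, s)
  }
  out
}

binary_dilate <- function(m, offsets) {
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offsets))) out <- out | shift3(m, offsets[i, ], FALSE)
  out
}

binary_erode <- function(m, offsets) {
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offsets))) out <- out & shift3(m, offsets[i, ], TRUE)
  out
}

#' Grayscale morphological opening
#'
#' Erosion followed by dilation with a ball structuring element, applied to a
#' subtracted angiographic volume to suppress small-scale bright noise before
#' thresholding. Opening never increases intensities and is idempotent.
#'
#' @param vol an [image_volume()].
#' @param radius_vox ball radius in voxels (`0` = identity).
#' @return An [image_volume()] on the same grid.
#' @export
grayscale_open <- function(vol, radius_vox = 1L) {
  stopifnot(inherits(vol, "image_volume"))
  if (radius_vox < 0) stop("radius_vox must be >= 0", call. = FALSE)
  if (radius_vox == 0) return(vol)
  if (radius_vox > min(dim(vol$values)) / 2)
    stop("structuring element larger than half the grid extent", call. = FALSE)
  off <- ball_offsets(radius_vox)
  opened <- max_filter(min_filter(vol$values, off), off)
  image_volume(opened, vol$spacing, vol$origin, vol$modality)
}

#' Grayscale morphological closing
#'
#' Dilation followed by erosion; used on baseline (bone-scan) volumes so the
#' interstitial gaps internal to the wound coil wire merge into one solid
#' region before thresholding.
#'
#' @inheritParams grayscale_open
#' @return An [image_volume()] on the same grid.
#' @export
grayscale_close <- function(vol, radius_vox = 1L) {
  stopifnot(inherits(vol, "image_volume"))
  if (radius_vox < 0) stop("radius_vox must be >= 0", call. = FALSE)
  if (radius_vox == 0) return(vol)
  if (radius_vox > min(dim(vol$values)) / 2)
    stop("structuring element larger than half the grid extent", call. = FALSE)
  off <- ball_offsets(radius_vox)
  closed <- min_filter(max_filter(vol$values, off), off)
  image_volume(closed, vol$spacing, vol$origin, vol$modality)
}

# separable Gaussian smoothing, sigma in voxels, zero-padded borders
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    acc <- array(0, dim(a))
    for (i in seq_along(w)) {
      d <- c(0L, 0L, 0L)
      d[axis] <- i - r - 1L
      acc <- acc + w[i] * shift3(a, d, 0)
    }
    a <- acc
  }
  a
}

# 3x3x3 box majority vote; the curvature-regularisation step of the
# morphological level set (approximates mean-curvature motion)
binary_majority <- function(m) {
  cnt <- array(0L, dim(m))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    cnt <- cnt + shift3(m, c(dx, dy, dz), FALSE)
  cnt > 13L
}
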