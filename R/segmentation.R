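# Segmentation of the vascular lumen (subtracted scans) and the coil mass
# (baseline scans): grayscale opening/closing, Otsu thresholding, connected
# components, internal-hole filling and a morphological level set.

#' Otsu's threshold by exhaustive search
#'
#' Finds the intensity threshold maximizing the between-class variance of the
#' sample, searching every candidate split between consecutive distinct
#' values. The returned threshold is the midpoint of the best split, so it
#' always lies strictly between the two classes; ties are broken toward the
#' lower threshold. Foreground is `values >= threshold`.
#'
#' @param values numeric vector (or array) of intensities; at least two
#'   distinct finite values.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  sv <- sort(v)
  r <- rle(sv)
  u <- r$values
  cnt <- r$lengths
  m <- length(u)
  if (m < 2) stop("degenerate histogram: all values identical", call. = FALSE)
  n <- length(sv)
  cw <- cumsum(cnt)                   # class-0 counts for split after i
  cs <- cumsum(cnt * u)               # class-0 intensity sums
  tot <- cs[m]
  i <- seq_len(m - 1)
  w0 <- cw[i] / n
  w1 <- 1 - w0
  mu0 <- cs[i] / cw[i]
  mu1 <- (tot - cs[i]) / (n - cw[i])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(bcv)              # which.max takes the first (lowest) tie
  (u[best] + u[best + 1]) / 2
}

#' Label connected components of a 3D mask
#'
#' @param mask a [binary_mask()] or logical array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  m <- if (inherits(mask, "binary_mask")) mask$values else mask
  stopifnot(connectivity %in% c(6L, 26L))
  .cw_label_components(m, dim(m), as.integer(connectivity))
}

#' Fill internal holes of a mask, retaining through-tunnels
#'
#' Background components that do not reach the grid boundary are enclosed
#' cavities and are filled; background components connected to the boundary
#' — including tunnels passing all the way through the solid, which make it
#' non-simply connected — are retained. A hole bounded on all sides by coil
#' wire can be attributed to the coil mass; a through-hole cannot, since
#' nothing bounds it at its mouths.
#'
#' @param mask a [binary_mask()].
#' @param connectivity background connectivity, 6 (default) or 26. Foreground
#'   26 / background 6 is the standard complementary pairing.
#' @return A [binary_mask()] containing the input (`output >= input`).
#' @export
fill_internal_holes <- function(mask, connectivity = 6L) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values
  if (!any(m)) stop("mask is empty", call. = FALSE)
  bg <- !m
  lab <- .cw_label_components(bg, dim(m), as.integer(connectivity))
  d <- dim(m)
  border_labels <- unique(c(
    lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
    lab[, , 1], lab[, , d[3]]
  ))
  border_labels <- border_labels[border_labels > 0]
  cavities <- bg & !(array(lab %in% border_labels, d))
  binary_mask(m | cavities, mask$spacing, mask$origin)
}

#' Default level-set parameters
#'
#' @return named list: `iterations` (front evolution steps; the front moves at
#'   most one voxel per step), `curvature_weight` (number of 3x3x3 majority
#'   smoothing passes per step), `propagation_weight` (kept for interface
#'   symmetry; region attachment weight), `edge_sigma` (Gaussian presmoothing
#'   of the image, in voxels).
#' @export
levelset_params <- function(iterations = 50L, curvature_weight = 1,
                            propagation_weight = 1, edge_sigma = 0.5) {
  list(iterations = as.integer(iterations),
       curvature_weight = curvature_weight,
       propagation_weight = propagation_weight,
       edge_sigma = edge_sigma)
}

#' Refine a segmentation with a morphological level set
#'
#' Region-based (Chan-Vese style) active contour implemented with morphology:
#' at each step, voxels in the one-voxel band around the current front are
#' reassigned to whichever side's mean intensity they are closer to, then the
#' front is regularized by `curvature_weight` passes of a 3x3x3 majority
#' vote (a discrete approximation of mean-curvature motion). The front moves
#' at most one voxel per iteration, so the result is confined to the initial
#' mask dilated by `iterations` voxels. Fully deterministic.
#'
#' @param vol an [image_volume()].
#' @param init a nonempty [binary_mask()] on the same grid.
#' @param params see [levelset_params()].
#' @return A refined [binary_mask()].
#' @export
levelset_refine <- function(vol, init, params = levelset_params()) {
  stopifnot(inherits(vol, "image_volume"), inherits(init, "binary_mask"))
  if (!same_grid(vol, init)) stop("grid mismatch", call. = FALSE)
  u <- init$values
  if (!any(u)) stop("initial mask is empty", call. = FALSE)
  p <- utils::modifyList(levelset_params(), params)
  if (p$iterations == 0L) return(init)
  img <- vol$values
  if (p$edge_sigma > 0) img <- gaussian_smooth3(img, p$edge_sigma)
  d <- dim(u)
  off6 <- ball_offsets(1)
  nsmooth <- max(0L, as.integer(round(p$curvature_weight)))
  for (it in seq_len(p$iterations)) {
    if (!any(u) || all(u)) break
    c1 <- mean(img[u])
    c0 <- mean(img[!u])
    du <- .cw_binary_morph(u, d, off6, 0L)
    eu <- .cw_binary_morph(u, d, off6, 1L)
    band <- du & !eu
    # reassign band voxels to the nearer class mean (region attachment)
    inside <- (img - c0)^2 * p$propagation_weight > (img - c1)^2
    u[band] <- inside[band]
    for (s in seq_len(nsmooth)) u <- .cw_box_majority(u, d)
  }
  if (!any(u)) stop("level set collapsed to an empty region", call. = FALSE)
  binary_mask(u, vol$spacing, vol$origin)
}

# crop box (mm) -> logical array selecting the VOI
voi_select <- function(vol, voi) {
  if (is.null(voi)) return(NULL)
  co <- coord_arrays(dim(vol$values), vol$spacing, vol$origin)
  co$x >= voi$min[1] & co$x <= voi$max[1] &
    co$y >= voi$min[2] & co$y <= voi$max[2] &
    co$z >= voi$min[3] & co$z <= voi$max[3]
}

#' Segment the vascular lumen from a subtracted volume
#'
#' Chain: grayscale opening, Otsu threshold over the volume of interest, the
#' connected component containing the seed, level-set refinement. The seed
#' only initializes the segmentation: any seed placed in the same
#' thresholded component yields an identical mask.
#'
#' @param subtracted subtracted-modality [image_volume()].
#' @param seed_point physical coordinates (mm) of a point inside the sac (or
#'   vessel) lumen.
#' @param voi optional volume of interest, `list(min = c(x,y,z), max =
#'   c(x,y,z))` in mm, over which the threshold is estimated; default the
#'   whole grid.
#' @param open_radius opening ball radius in voxels.
#' @param levelset parameters for [levelset_refine()].
#' @return A [binary_mask()] of lumen (vessels + any sac/residual blood).
#' @export
segment_vascular <- function(subtracted, seed_point, voi = NULL,
                             open_radius = 1L, levelset = levelset_params()) {
  stopifnot(inherits(subtracted, "image_volume"))
  d <- dim(subtracted$values)
  sv <- point_to_voxel(seed_point, subtracted$spacing, subtracted$origin, d)
  opened <- grayscale_open(subtracted, open_radius)
  sel <- voi_select(opened, voi)
  sample_vals <- if (is.null(sel)) opened$values else opened$values[sel]
  thr <- otsu_threshold(sample_vals)
  fg <- opened$values >= thr
  if (!fg[sv[1], sv[2], sv[3]])
    stop("seed point falls in background after thresholding; ",
         "place the seed inside the contrast-filled lumen", call. = FALSE)
  lab <- .cw_label_components(fg, d, 26L)
  comp <- lab == lab[sv[1], sv[2], sv[3]]
  init <- binary_mask(array(comp, d), subtracted$spacing, subtracted$origin)
  ref <- levelset_refine(opened, init, levelset)
  # the level set may nibble the component apart; keep the seeded piece
  lab2 <- .cw_label_components(ref$values, d, 26L)
  seed_lab <- lab2[sv[1], sv[2], sv[3]]
  if (seed_lab == 0) {
    # seed voxel itself fell outside after refinement: take nearest component
    keep <- ref$values
  } else {
    keep <- array(lab2 == seed_lab, d)
  }
  binary_mask(keep, subtracted$spacing, subtracted$origin)
}

#' Segment the coil mass from a baseline (bone-scan) volume
#'
#' Chain: grayscale closing (dilate then erode, merging the interstices
#' internal to the bounding coil wire), Otsu threshold, largest connected
#' component, internal-hole filling with through-tunnel retention, level-set
#' refinement, and a final largest-component + hole-fill pass. The resulting
#' region stands for the coil wires together with interstitial thrombus —
#' the coil mass.
#'
#' @param baseline baseline-modality [image_volume()].
#' @param close_radius closing ball radius in voxels.
#' @param voi optional volume of interest (mm box, as in
#'   [segment_vascular()]) over which the threshold is estimated. Strongly
#'   recommended whenever the coil occupies a small fraction of the scan:
#'   Otsu's bimodality assumption degrades when one class is rare.
#' @param levelset parameters for [levelset_refine()].
#' @param fill_connectivity background connectivity for hole filling.
#' @return A [binary_mask()] of the coil mass.
#' @export
segment_coil <- function(baseline, close_radius = 1L, voi = NULL,
                         levelset = levelset_params(),
                         fill_connectivity = 6L) {
  stopifnot(inherits(baseline, "image_volume"))
  if (baseline$modality != "baseline")
    warning("segment_coil expects a baseline (bone-scan) volume")
  d <- dim(baseline$values)
  closed <- grayscale_close(baseline, close_radius)
  sel <- voi_select(closed, voi)
  thr <- otsu_threshold(if (is.null(sel)) closed$values
                        else closed$values[sel])
  fg <- closed$values >= thr
  if (!any(fg))
    stop("no foreground after thresholding: no coil in the field of view",
         call. = FALSE)
  lab <- .cw_label_components(fg, d, 26L)
  counts <- tabulate(lab[lab > 0])
  keep <- array(lab == which.max(counts), d)
  init <- fill_internal_holes(
    binary_mask(keep, baseline$spacing, baseline$origin), fill_connectivity)
  ref <- levelset_refine(closed, init, levelset)
  lab2 <- .cw_label_components(ref$values, d, 26L)
  counts2 <- tabulate(lab2[lab2 > 0])
  keep2 <- array(lab2 == which.max(counts2), d)
  fill_internal_holes(
    binary_mask(keep2, baseline$spacing, baseline$origin), fill_connectivity)
}
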