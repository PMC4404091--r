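#' 3D image volume
#'
#' A minimal container for a 3D scalar image: a numeric array plus isotropic
#' or anisotropic voxel spacing (mm), a physical origin (mm, the center of
#' voxel `[1,1,1]`) and a modality tag. Subtracted angiographic volumes show
#' the contrast-filled lumen (vessels plus any blood in the aneurysm sac);
#' baseline (bone-scan) volumes show only radio-dense structures, i.e. the
#' coil mass (and skull, outside a cropped volume of interest).
#'
#' @param values numeric 3D array of intensities.
#' @param spacing voxel spacing in mm; length 1 (isotropic) or 3.
#' @param origin physical coordinate (mm) of the center of the first voxel.
#' @param modality `"subtracted"` or `"baseline"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = 0.22, origin = c(0, 0, 0),
                         modality = c("subtracted", "baseline")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  origin <- rep_len(as.numeric(origin), 3L)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality),
    class = "image_volume"
  )
}

#' Binary segmentation mask
#'
#' A boolean 3D array on the same grid as the image it was derived from.
#'
#' @param values logical 3D array.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = 0.22, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "logical"
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  origin <- rep_len(as.numeric(origin), 3L)
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "binary_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " mm, modality ", x$modality, "\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$values), collapse = "x"),
      " voxels, ", sum(x$values), " foreground\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Voxel center coordinates along each axis
#' @noRd
axis_coords <- function(dims, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
}

#' Physical coordinates (mm) of every voxel center, as three arrays
#' @noRd
coord_arrays <- function(dims, spacing, origin) {
  ax <- axis_coords(dims, spacing, origin)
  list(
    x = array(rep(ax[[1]], times = dims[2] * dims[3]), dims),
    y = array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims),
    z = array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  )
}

#' Convert a physical point (mm) to the nearest voxel index
#' @noRd
point_to_voxel <- function(pt, spacing, origin, dims) {
  v <- round((pt - origin) / spacing) + 1
  v <- pmin(pmax(v, 1), dims)
  as.integer(v)
}

#' Voxel volume in cc (1 cc = 1000 mm^3)
#' @noRd
voxel_cc <- function(spacing) prod(spacing) / 1000

#' Physical coordinates of the foreground voxel nearest to a point
#' @noRd
snap_to_mask <- function(mask, pt) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
  xyz <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  d2 <- rowSums(sweep(xyz, 2, pt, `-`)^2)
  xyz[which.min(d2), ]
}

#' Voxel-count volume of a mask, in cc
#'
#' The simple counting estimator: number of foreground voxels times the voxel
#' volume. Used as the independent volumetric oracle against which the
#' mesh-based (divergence-theorem) volume is validated.
#'
#' @param mask a [binary_mask()].
#' @return volume in cc.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_cc(mask$spacing)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}. Spacing is stored in the NIfTI pixdim;
#' modality is not representable in the format and must be supplied on read.
#'
#' @param vol an [image_volume()].
#' @param path file path, conventionally `.nii` or `.nii.gz`.
#' @param modality modality tag to attach on read.
#' @return `write_volume` returns `path` invisibly; `read_volume` an
#'   [image_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, modality = c("subtracted", "baseline")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3], modality = modality)
}
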