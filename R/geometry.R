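# Watertight surface models from voxel masks, divergence-theorem volumetry
# and centroid integration, and isolation of the aneurysm sac from the
# contiguous vasculature with a non-planar neck surface.

#' Surface mesh constructor
#'
#' @param vertices numeric matrix (n x 3), physical mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices, outward
#'   oriented (counter-clockwise seen from outside).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, volume ", signif(mesh_volume(x), 4), " cc\n", sep = "")
  invisible(x)
}

# every undirected edge must be used by exactly two faces, once per direction
#' Check that a mesh is closed and consistently oriented
#' @param mesh a [surface_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- as.numeric(nrow(mesh$vertices))
  dir_key <- (e[, 1] - 1) * nv + e[, 2]
  und_key <- (pmin(e[, 1], e[, 2]) - 1) * nv + pmax(e[, 1], e[, 2])
  if (anyDuplicated(dir_key) > 0) return(FALSE)
  s <- sort(und_key)
  if (length(s) %% 2 != 0) return(FALSE)
  p1 <- s[seq(1, length(s), 2)]
  p2 <- s[seq(2, length(s), 2)]
  all(p1 == p2) && anyDuplicated(p1) == 0
}

stop_if_open <- function(mesh) {
  if (!is_watertight(mesh))
    stop("mesh is not watertight/consistently oriented", call. = FALSE)
}

# signed tetrahedron volumes to the origin, one per face, in mm^3
signed_tet_volumes <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
     a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
     a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Mesh volume by the divergence theorem
#'
#' Sums signed tetrahedra spanned by each face and the origin; exact for any
#' closed, consistently oriented triangulated surface. Reported positive, in
#' cc (1 cc = 1000 mm^3).
#'
#' @param mesh a watertight [surface_mesh()].
#' @return volume in cc.
#' @export
mesh_volume <- function(mesh) {
  stop_if_open(mesh)
  abs(sum(signed_tet_volumes(mesh))) / 1000
}

#' Volume-weighted mesh centroid by numerical integration
#'
#' Signed-tetrahedron integration of the first moment: each face contributes
#' its tetrahedron-to-origin centroid weighted by signed volume. Exact for
#' watertight meshes; translation- and rotation-equivariant.
#'
#' @param mesh a watertight [surface_mesh()].
#' @return centroid, length-3 numeric (mm).
#' @export
mesh_centroid <- function(mesh) {
  stop_if_open(mesh)
  w <- signed_tet_volumes(mesh)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  tot <- sum(w)
  if (abs(tot) < 1e-12) stop("mesh has zero volume", call. = FALSE)
  # tetrahedron centroid = (origin + a + b + c) / 4
  as.numeric(colSums(w * (a + b + c_) / 4) / tot)
}

#' Triangulated isosurface of a binary mask
#'
#' Marching tetrahedra (Kuhn cube subdivision, watertight by construction) at
#' the 0.5 level of the Gaussian-smoothed foreground indicator. Smoothing
#' (sigma in voxels) reduces the stair-step volume bias of a binary
#' isosurface; foreground voxel centers are clamped to remain inside the
#' surface so single-voxel-scale structures survive the smoothing. The field
#' is zero-padded, so masks touching the grid boundary still close.
#'
#' @param mask a nonempty [binary_mask()].
#' @param smooth_sigma Gaussian sigma in voxels (0 disables smoothing).
#' @return A [surface_mesh()] in physical mm.
#' @export
extract_surface <- function(mask, smooth_sigma = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values
  if (!any(m)) stop("mask is empty", call. = FALSE)
  ind <- array(as.numeric(m), dim(m))
  field <- if (smooth_sigma > 0) {
    pmax(gaussian_smooth3(ind, smooth_sigma), ind)
  } else ind
  res <- .cw_march_tets(field, dim(m), 0.5, mask$spacing, mask$origin, 0)
  surface_mesh(res$vertices, res$faces)
}

#' Voxelwise union of two masks on one grid
#'
#' @param a,b [binary_mask()] objects with identical shape, spacing, origin.
#' @return A [binary_mask()].
#' @export
mask_union <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a, b))
    stop("masks are on different grids; resample one onto the other first",
         call. = FALSE)
  binary_mask(a$values | b$values, a$spacing, a$origin)
}

#' Sac model constructor
#' @noRd
sac_model <- function(mesh, neck_boundary, mask) {
  structure(
    list(mesh = mesh, neck_boundary = neck_boundary,
         volume_cc = mesh_volume(mesh), mask = mask),
    class = "sac_model"
  )
}

#' @export
print.sac_model <- function(x, ...) {
  cat("<sac_model> volume ", signif(x$volume_cc, 4), " cc, ",
      length(x$neck_boundary), " neck vertices\n", sep = "")
  invisible(x)
}

# auto centerline: endpoints are the two largest clusters of foreground on
# the grid boundary (where the parent vessel leaves the field of view);
# the path between them follows maximal inscribed spheres (geodesic with
# inverse-distance cost), i.e. the lumen centerline.
auto_centerline <- function(m, spacing, edt) {
  d <- dim(m)
  onb <- array(FALSE, d)
  onb[1, , ] <- TRUE; onb[d[1], , ] <- TRUE
  onb[, 1, ] <- TRUE; onb[, d[2], ] <- TRUE
  onb[, , 1] <- TRUE; onb[, , d[3]] <- TRUE
  shell <- m & onb
  if (!any(shell))
    stop("no vessel reaches the grid boundary; supply vessel_info",
         call. = FALSE)
  lab <- .cw_label_components(shell, d, 26L)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) < 2)
    stop("could not find two vessel ends on the grid boundary; ",
         "supply vessel_info", call. = FALSE)
  ord <- order(sizes, decreasing = TRUE)[1:2]
  pick <- function(l) {
    idx <- which(lab == l)
    idx[which.max(edt[idx])]
  }
  s <- pick(ord[1]); e <- pick(ord[2])
  cost <- 1 / (edt + 0.1)
  path <- .cw_dijkstra_path(m, d, spacing, as.numeric(cost),
                            as.integer(s), as.integer(e))
  if (nrow(path) == 0)
    stop("vessel ends are not connected through the mask", call. = FALSE)
  path
}

#' Isolate the aneurysm sac with a non-planar neck surface
#'
#' Removes the parent vessel by centerline tube subtraction: the lumen
#' centerline is traced (automatically between the two points where the
#' vessel crosses the grid boundary, or along a supplied polyline), the local
#' vessel caliber is taken as the maximal-inscribed-sphere radius from the
#' distance transform, and a tube of `tube_scale` times that radius is swept
#' along the centerline and subtracted from the mask. The connected remnant
#' containing the seed is the sac; meshing the remnant closes it across the
#' former vessel interface, producing a neck surface that follows the local
#' tube geometry rather than a single cutting plane.
#'
#' @param mask [binary_mask()] of the vessel complex (vessels + sac, or the
#'   union of coil mass and residual blood with the vessels).
#' @param sac_seed physical point (mm) inside the sac bulge.
#' @param vessel_info optional list with `path` (n x 3 matrix, mm) and
#'   optionally `radius` (mm, scalar or per-point) overriding the traced
#'   centerline / measured caliber.
#' @param tube_scale multiplier on the local inscribed-sphere radius.
#' @param radius_cap_factor cap on the local caliber, as a multiple of the
#'   median caliber along the centerline (prevents the tube from swallowing
#'   the sac where the inscribed sphere leaks into it).
#' @param smooth_sigma passed to [extract_surface()].
#' @return A `sac_model`: `mesh`, `neck_boundary` (vertex indices on the
#'   capped neck), `volume_cc`, and the remnant voxel `mask`.
#' @export
isolate_sac <- function(mask, sac_seed, vessel_info = NULL, tube_scale = 1.1,
                        radius_cap_factor = 1.5, smooth_sigma = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values
  if (!any(m)) stop("mask is empty", call. = FALSE)
  d <- dim(m)
  sp <- mask$spacing
  edt <- .cw_edt(m, d, sp, 0L)  # unbounded: true caliber at the grid faces

  if (is.null(vessel_info)) {
    pvox <- auto_centerline(m, sp, edt)
    pts <- cbind(mask$origin[1] + (pvox[, 1] - 1) * sp[1],
                 mask$origin[2] + (pvox[, 2] - 1) * sp[2],
                 mask$origin[3] + (pvox[, 3] - 1) * sp[3])
    rloc <- edt[cbind(pvox[, 1], pvox[, 2], pvox[, 3])]
  } else {
    pts <- as.matrix(vessel_info$path)
    # resample the polyline at ~half-voxel steps so sphere sweeping is smooth
    pts <- resample_polyline(pts, min(sp) / 2)
    if (!is.null(vessel_info$radius)) {
      rloc <- rep_len(vessel_info$radius, nrow(pts))
    } else {
      pv <- t(vapply(seq_len(nrow(pts)), function(i)
        point_to_voxel(pts[i, ], sp, mask$origin, d), integer(3)))
      rloc <- edt[cbind(pv[, 1], pv[, 2], pv[, 3])]
    }
  }
  # the voxel EDT undershoots the continuous inscribed radius by up to half
  # a voxel (the centerline voxel center is off the true axis); compensate
  rloc <- rloc + 0.5 * min(sp)
  rloc <- pmin(rloc, radius_cap_factor * stats::median(rloc))
  rtube <- tube_scale * rloc

  # sweep spheres of local radius along the centerline
  tube <- array(FALSE, d)
  co <- coord_arrays(d, sp, mask$origin)
  rmax <- max(rtube)
  for (i in seq_len(nrow(pts))) {
    lo <- point_to_voxel(pts[i, ] - rmax - min(sp), sp, mask$origin, d)
    hi <- point_to_voxel(pts[i, ] + rmax + min(sp), sp, mask$origin, d)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx <- co$x[xs, ys, zs] - pts[i, 1]
    dy <- co$y[xs, ys, zs] - pts[i, 2]
    dz <- co$z[xs, ys, zs] - pts[i, 3]
    tube[xs, ys, zs] <- tube[xs, ys, zs] | (dx * dx + dy * dy + dz * dz <=
                                              rtube[i]^2)
  }

  remnant <- m & !tube
  if (!any(remnant))
    stop("no sac found: nothing remains after parent-vessel removal",
         call. = FALSE)
  sv <- point_to_voxel(sac_seed, sp, mask$origin, d)
  lab <- .cw_label_components(remnant, d, 26L)
  seed_lab <- lab[sv[1], sv[2], sv[3]]
  if (seed_lab == 0) {
    # tolerate a seed voxel grazed by the tube: snap within 2 voxels
    off <- ball_offsets(2)
    cand <- sweep(off, 2, sv, `+`)
    ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
      cand[, 1] <= d[1] & cand[, 2] <= d[2] & cand[, 3] <= d[3]
    labs <- lab[cand[ok, , drop = FALSE]]
    labs <- labs[labs > 0]
    if (length(labs) == 0)
      stop("no sac found at the seed point after parent-vessel removal; ",
           "re-seed inside the sac bulge", call. = FALSE)
    seed_lab <- labs[1]
  }
  sac <- array(lab == seed_lab, d)
  if (sum(sac) < 8)
    stop("no sac found: remnant at the seed is below the resolution limit",
         call. = FALSE)
  sac_mask <- binary_mask(sac, sp, mask$origin)
  mesh <- extract_surface(sac_mask, smooth_sigma)

  # neck vertices: mesh vertices adjacent to the removed tube region
  vv <- mesh$vertices
  vvox <- cbind(
    pmin(pmax(round((vv[, 1] - mask$origin[1]) / sp[1]) + 1, 1), d[1]),
    pmin(pmax(round((vv[, 2] - mask$origin[2]) / sp[2]) + 1, 1), d[2]),
    pmin(pmax(round((vv[, 3] - mask$origin[3]) / sp[3]) + 1, 1), d[3])
  )
  near_tube <- .cw_binary_morph(tube & m, d, ball_offsets(1), 0L)
  neck <- which(near_tube[vvox])
  sac_model(mesh, neck, sac_mask)
}

# resample a polyline to roughly equal steps
resample_polyline <- function(pts, step) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  at <- seq(0, total, by = step)
  if (at[length(at)] < total) at <- c(at, total)
  t(vapply(at, function(a) {
    i <- findInterval(a, s, rightmost.closed = TRUE)
    i <- min(i, nrow(pts) - 1)
    f <- if (seg[i] > 0) (a - s[i]) / seg[i] else 0
    pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }, numeric(3)))
}

#' Post-treatment sac model from coil and angiographic masks
#'
#' After coiling the sac is no longer directly visible on the subtracted
#' scan: it is the combination of the coil mass and any outlying residual
#' blood. The two masks are joined by Boolean union, the surface extracted,
#' and the sac isolated from the contiguous vessels.
#'
#' @param coil_mask coil-mass [binary_mask()] (from the baseline scan).
#' @param angio_mask vascular [binary_mask()] (from the subtracted scan).
#' @param sac_seed physical point (mm) inside the sac.
#' @param ... passed to [isolate_sac()].
#' @return A `sac_model`.
#' @export
build_posttreatment_sac <- function(coil_mask, angio_mask, sac_seed, ...) {
  u <- mask_union(coil_mask, angio_mask)
  if (!any(u$values)) stop("empty union: no coil and no residual blood",
                           call. = FALSE)
  isolate_sac(u, sac_seed, ...)
}

#' Write / read meshes as ASCII STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `write_mesh_stl` returns `path` invisibly; `read_mesh_stl` a
#'   [surface_mesh()] (vertices deduplicated).
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid coilwatch", con)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  txt <- vapply(seq_len(nrow(f)), function(i) {
    paste0("facet normal ", paste(format(n[i, ], digits = 9), collapse = " "),
           "\n outer loop\n  vertex ",
           paste(format(a[i, ], digits = 9), collapse = " "),
           "\n  vertex ", paste(format(b[i, ], digits = 9), collapse = " "),
           "\n  vertex ", paste(format(c_[i, ], digits = 9), collapse = " "),
           "\n endloop\nendfacet")
  }, character(1))
  writeLines(txt, con)
  writeLines("endsolid coilwatch", con)
  invisible(path)
}

#' @rdname write_mesh_stl
#' @export
read_mesh_stl <- function(path) {
  ln <- trimws(readLines(path))
  vx <- ln[startsWith(ln, "vertex")]
  xyz <- do.call(rbind, lapply(strsplit(sub("^vertex +", "", vx), " +"),
                               as.numeric))
  key <- apply(xyz, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}
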