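# Mesh extraction, divergence-theorem volumetry, centroid integration, mask
# union and sac isolation.

test_that("extract_surface produces watertight meshes with correct volume", {
  m <- array(FALSE, c(14, 14, 14))
  m[3:12, 3:12, 3:12] <- TRUE
  bm <- binary_mask(m, spacing = 1)
  mesh <- extract_surface(bm)
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_volume(mesh) * 1000 - 1000) / 1000, 0.05)

  single <- binary_mask(array(FALSE, c(7, 7, 7)), 1)
  single$values[4, 4, 4] <- TRUE
  ms <- extract_surface(single)
  expect_true(is_watertight(ms))
  v <- mesh_volume(ms) * 1000
  expect_gte(v, 0.5)
  expect_lte(v, 2)

  expect_error(extract_surface(binary_mask(array(FALSE, c(5, 5, 5)), 1)),
               "empty")

  # translation equivariance (shift keeps the solid off the grid border)
  m_small <- array(FALSE, c(14, 14, 14))
  m_small[3:10, 3:10, 3:10] <- TRUE
  mesh <- extract_surface(binary_mask(m_small, 1))
  shifted <- binary_mask(coilwatch:::shift3(m_small, c(2, 0, 0), FALSE), 1)
  mesh2 <- extract_surface(shifted)
  expect_equal(mesh_volume(mesh2), mesh_volume(mesh), tolerance = 1e-10)
  expect_equal(mesh_centroid(mesh2), mesh_centroid(mesh) + c(2, 0, 0),
               tolerance = 1e-8)
})

test_that("mesh volume matches closed forms on analytic meshes", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  expect_true(is_watertight(cube))
  expect_equal(mesh_volume(cube), 0.001)          # 1 mm^3 exactly
  expect_equal(mesh_centroid(cube), c(0.5, 0.5, 0.5))

  ico <- icosphere(radius = 5, center = c(3, 4, 5), subdivisions = 4)
  expect_true(is_watertight(ico))
  expect_lt(abs(mesh_volume(ico) / 0.5236 - 1), 0.01)
  expect_equal(mesh_centroid(ico), c(3, 4, 5), tolerance = 1e-6)

  # translation invariance of volume
  far <- surface_mesh(sweep(ico$vertices, 2, c(100, 100, 100), `+`),
                      ico$faces)
  expect_equal(mesh_volume(far), mesh_volume(ico), tolerance = 1e-9)

  # open mesh rejected
  open_mesh <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "watertight")
  expect_error(mesh_centroid(open_mesh), "watertight")
})

test_that("centroid integration is exact on composite solids", {
  # L-solid: two unit cubes sharing the x = 1 face
  a <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  b <- box_mesh(c(1, 0, 0), c(2, 1, 1))
  # combine as one voxel solid instead: fine-grid L mask
  d <- c(46, 26, 26)
  sp <- 0.05
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - 1) * sp)
  x <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  L <- x >= 0.1 & x < 2.1 & y >= 0.1 & y < 1.1 & z >= 0.1 & z < 1.1
  mesh <- extract_surface(binary_mask(L, sp))
  expect_equal(mesh_centroid(mesh), c(1.075, 0.575, 0.575), tolerance = 0.02)
  expect_lt(abs(mesh_volume(mesh) * 1000 - 2) / 2, 0.05)

  # mass-weighted average of the two analytic cubes
  va <- mesh_volume(a); vb <- mesh_volume(b)
  comb <- (va * mesh_centroid(a) + vb * mesh_centroid(b)) / (va + vb)
  expect_equal(comb, c(1, 0.5, 0.5))
})

test_that("mask union obeys set algebra on one grid", {
  a <- sphere_mask(c(24, 24, 24), 1, c(8, 11.5, 11.5), 4)
  b <- sphere_mask(c(24, 24, 24), 1, c(17, 11.5, 11.5), 4)
  empty <- binary_mask(array(FALSE, c(24, 24, 24)), 1)
  expect_identical(mask_union(a, empty)$values, a$values)
  expect_identical(mask_union(a, a)$values, a$values)
  expect_equal(sum(mask_union(a, b)$values), sum(a$values) + sum(b$values))
  expect_lte(mask_volume_cc(mask_union(a, b)),
             mask_volume_cc(a) + mask_volume_cc(b))

  other <- sphere_mask(c(20, 20, 20), 1, c(8, 8, 8), 4)
  expect_error(mask_union(a, other), "resampl")
})

test_that("sac isolation recovers a sphere on a vessel with a non-planar neck", {
  ts <- tube_sphere_volume(dims = c(64, 64, 64), sphere_r = 5, tube_r = 1.5,
                           noise_sd = 0)
  mask <- binary_mask(ts$truth_sphere | ts$truth_tube, ts$spacing)
  sm <- isolate_sac(mask, ts$sphere_center)
  expect_true(is_watertight(sm$mesh))
  expect_lt(abs(sm$volume_cc / 0.5236 - 1), 0.10)
  expect_gt(length(sm$neck_boundary), 0)
  expect_equal(sm$volume_cc, mesh_volume(sm$mesh))

  # seed insensitivity within the sac
  sm2 <- isolate_sac(mask, ts$sphere_center + c(1.2, 0.8, -0.6))
  expect_equal(sm2$volume_cc, sm$volume_cc)

  # a straight tube with no bulge has no sac
  tube_only <- binary_mask(ts$truth_tube, ts$spacing)
  seed_in_tube <- c(ts$sphere_center[1],
                    ts$sphere_center[2] - 0.92 * 6.5, ts$sphere_center[3])
  expect_error(isolate_sac(tube_only, seed_in_tube), "no sac")
})

test_that("supplied vessel polylines drive the tube subtraction", {
  ts <- tube_sphere_volume(dims = c(48, 48, 48), sphere_r = 2.2, tube_r = 1,
                           noise_sd = 0)
  mask <- binary_mask(ts$truth_sphere | ts$truth_tube, ts$spacing)
  ext <- (dim(mask$values) - 1) * ts$spacing
  y0 <- ts$sphere_center[2] - 0.92 * 3.2
  vi <- list(path = rbind(c(0, y0, ts$sphere_center[3]),
                          c(ext[1], y0, ts$sphere_center[3])),
             radius = 1)
  sm <- isolate_sac(mask, ts$sphere_center, vessel_info = vi)
  truth_cc <- 4 / 3 * pi * 2.2^3 / 1000
  expect_lt(abs(sm$volume_cc / truth_cc - 1), 0.10)
})

test_that("post-treatment sacs are unions of coil and residual blood", {
  scn <- scenario(sac_semiaxes = c(2.5, 2.5, 2.5), grid_shape = c(48, 48, 48),
                  seed = 23, noise_sd = 0, artifact_level = 0)
  subj <- make_subject(scn)
  e <- subj$timepoints[["1p"]]
  coil <- binary_mask(e$baseline$values > 55, scn$spacing)
  angio <- binary_mask(e$subtracted$values > 55, scn$spacing)
  sm <- build_posttreatment_sac(coil, angio, subj$seeds$sac[["1p"]])
  expect_lt(abs(sm$volume_cc / subj$truth$true_sac_volume_cc[["1p"]] - 1),
            0.10)
  empty <- binary_mask(array(FALSE, dim(coil$values)), scn$spacing)
  expect_error(build_posttreatment_sac(empty, empty, subj$seeds$sac[["1p"]]),
               "empty")
})

test_that("meshes survive an STL round trip", {
  ico <- icosphere(radius = 2, center = c(5, 5, 5), subdivisions = 2)
  tmp <- tempfile(fileext = ".stl")
  write_mesh_stl(ico, tmp)
  back <- read_mesh_stl(tmp)
  expect_true(is_watertight(back))
  expect_equal(mesh_volume(back), mesh_volume(ico), tolerance = 1e-6)
  expect_equal(mesh_centroid(back), mesh_centroid(ico), tolerance = 1e-6)
})
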