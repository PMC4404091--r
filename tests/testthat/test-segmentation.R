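# Segmentation layer: morphology, Otsu, hole filling, level set, and the
# vascular/coil chains on phantoms with known ground truth.

test_that("grayscale opening removes speckle and respects its contracts", {
  set.seed(1)
  img <- array(10 + rnorm(20^3, 0, 1), c(20, 20, 20))
  vol <- image_volume(img, spacing = 1)
  expect_identical(grayscale_open(vol, 0L)$values, vol$values)

  spike <- array(10, c(20, 20, 20))
  spike[10, 10, 10] <- 200
  vs <- image_volume(spike, spacing = 1)
  opened <- grayscale_open(vs, 1L)
  expect_equal(opened$values[10, 10, 10], 10)       # speckle removed
  expect_true(all(opened$values <= vs$values))      # anti-extensive
  reopened <- grayscale_open(opened, 1L)
  expect_equal(reopened$values, opened$values)      # idempotent

  const <- image_volume(array(7, c(12, 12, 12)), spacing = 1)
  expect_equal(grayscale_open(const, 1L)$values, const$values)
  expect_error(grayscale_open(const, 40L), "half the grid")
})

test_that("otsu threshold splits modes and matches an exhaustive oracle", {
  thr <- otsu_threshold(c(rep(0, 50), rep(100, 50)))
  expect_gt(thr, 0)
  expect_lt(thr, 100)

  expect_equal(otsu_threshold(c(0, 1)), 0.5)

  set.seed(7)
  v <- c(rnorm(400, 10, 5), rnorm(400, 200, 5))
  thr2 <- otsu_threshold(v)
  expect_gt(thr2, 25)
  expect_lt(thr2, 185)

  expect_error(otsu_threshold(rep(3, 10)), "degenerate")

  # brute-force oracle: maximize between-class variance over all splits
  oracle <- function(v) {
    u <- sort(unique(v))
    n <- length(v)
    best <- -Inf; bt <- NA
    for (i in seq_len(length(u) - 1)) {
      t <- (u[i] + u[i + 1]) / 2
      lo <- v[v < t]; hi <- v[v >= t]
      bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
      if (bcv > best + 1e-12) { best <- bcv; bt <- t }
    }
    bt
  }
  set.seed(42)
  for (rep in 1:20) {
    v <- sample(0:20, 60, replace = TRUE) +
      100 * rbinom(60, 1, 0.5)
    expect_equal(otsu_threshold(v), oracle(v))
  }
})

test_that("internal cavities are filled, through-tunnels and solids untouched", {
  shell <- sphere_mask(c(24, 24, 24), 1, c(11.5, 11.5, 11.5), 8)
  core <- sphere_mask(c(24, 24, 24), 1, c(11.5, 11.5, 11.5), 5)
  hollow <- binary_mask(shell$values & !core$values, 1)
  filled <- fill_internal_holes(hollow)
  expect_equal(filled$values, shell$values)
  expect_true(all(filled$values >= hollow$values))

  torus <- torus_mask(c(28, 28, 28), 1, c(13.5, 13.5, 13.5), 8, 3)
  expect_equal(fill_internal_holes(torus)$values, torus$values)

  cube <- binary_mask(array(TRUE, c(8, 8, 8)) &
                        array(c(TRUE), c(8, 8, 8)), 1)
  cube$values[c(1, 8), , ] <- FALSE
  expect_equal(fill_internal_holes(cube)$values, cube$values)
})

test_that("level set refines toward the true boundary and stays bounded", {
  ts <- tube_sphere_volume(noise_sd = 0)
  truth <- binary_mask(ts$truth_sphere | ts$truth_tube, ts$spacing)

  expect_identical(
    levelset_refine(ts$vol, truth, levelset_params(iterations = 0))$values,
    truth$values)
  expect_error(levelset_refine(
    ts$vol, binary_mask(array(FALSE, dim(truth$values)), ts$spacing)),
    "empty")

  eroded <- binary_mask(
    coilwatch:::.cw_binary_morph(truth$values, dim(truth$values),
                                 coilwatch:::ball_offsets(1), 1L),
    ts$spacing)
  ref <- levelset_refine(ts$vol, eroded, levelset_params(iterations = 10))
  expect_gte(dice(ref$values, truth$values), 0.95)
  expect_gte(dice(ref$values, eroded$values), 0.5)

  # CFL-style bound: at most one voxel of front motion per iteration
  set.seed(3)
  noise <- image_volume(array(rnorm(32^3), c(32, 32, 32)), spacing = 1)
  init <- binary_mask(array(FALSE, c(32, 32, 32)), 1)
  init$values[15:17, 15:17, 15:17] <- TRUE
  iters <- 5L
  out <- levelset_refine(noise, init,
                         levelset_params(iterations = iters,
                                         curvature_weight = 0))
  idx <- which(out$values, arr.ind = TRUE)
  expect_true(all(idx[, 1] >= 15 - iters & idx[, 1] <= 17 + iters &
                    idx[, 2] >= 15 - iters & idx[, 2] <= 17 + iters &
                    idx[, 3] >= 15 - iters & idx[, 3] <= 17 + iters))
})

test_that("vascular segmentation recovers the lumen and ignores seed placement", {
  ts <- tube_sphere_volume(noise_sd = 5, seed = 2)
  ls <- levelset_params(iterations = 15)
  m1 <- segment_vascular(ts$vol, ts$sphere_center, levelset = ls)
  truth_cc <- sum(ts$truth_sphere | ts$truth_tube) * prod(rep(ts$spacing, 3)) / 1000
  expect_lt(abs(mask_volume_cc(m1) / truth_cc - 1), 0.05)

  m2 <- segment_vascular(ts$vol, ts$sphere_center + c(0.8, -0.5, 0.4),
                         levelset = ls)
  expect_identical(m1$values, m2$values)   # seed-insensitive
  m3 <- segment_vascular(ts$vol, ts$sphere_center, levelset = ls)
  expect_identical(m1$values, m3$values)   # deterministic

  expect_error(segment_vascular(ts$vol, c(0.5, 0.5, 0.5), levelset = ls),
               "re-seed|background")
})

test_that("coil segmentation recovers the coil solid with correct topology", {
  scn <- scenario(sac_semiaxes = c(2.5, 2.5, 2.5), grid_shape = c(48, 48, 48),
                  coil_fill_fraction = 0.3, seed = 17, noise_sd = 5)
  subj <- make_subject(scn)
  ls <- levelset_params(iterations = 15)
  coil <- segment_coil(subj$timepoints[["1p"]]$baseline,
                       voi = subj$seeds$voi, levelset = ls)
  truth <- subj$truth$true_coil_volume_cc[["1p"]]
  expect_lt(abs(mask_volume_cc(coil) / truth - 1), 0.10)
  coil2 <- segment_coil(subj$timepoints[["1p"]]$baseline,
                        voi = subj$seeds$voi, levelset = ls)
  expect_identical(coil$values, coil2$values)

  # sealed internal cavity belongs to the coil mass; through-tunnel does not
  d <- c(36, 36, 36)
  shell <- sphere_mask(d, 0.25, c(4.4, 4.4, 4.4), 3)$values &
    !sphere_mask(d, 0.25, c(4.4, 4.4, 4.4), 1.5)$values
  img <- image_volume(10 + 90 * shell, spacing = 0.25, modality = "baseline")
  seg <- segment_coil(img, close_radius = 0L,
                      levelset = levelset_params(iterations = 0))
  ctr_vox <- c(18, 18, 18)
  expect_true(seg$values[ctr_vox[1], ctr_vox[2], ctr_vox[3]])  # cavity filled

  tor <- torus_mask(d, 0.25, c(4.4, 4.4, 4.4), 2.4, 1)$values
  imgt <- image_volume(10 + 90 * tor, spacing = 0.25, modality = "baseline")
  segt <- segment_coil(imgt, close_radius = 0L,
                       levelset = levelset_params(iterations = 0))
  expect_false(segt$values[ctr_vox[1], ctr_vox[2], ctr_vox[3]])  # tunnel kept

  flat <- image_volume(array(10, c(16, 16, 16)), spacing = 1,
                       modality = "baseline")
  expect_error(segment_coil(flat), "degenerate|no coil")
})

test_that("segmentation accuracy degrades monotonically with noise", {
  ls <- levelset_params(iterations = 15)
  dices <- sapply(c(0, 8, 16), function(ns) {
    ts <- tube_sphere_volume(noise_sd = ns, seed = 6)
    m <- segment_vascular(ts$vol, ts$sphere_center, levelset = ls)
    dice(m$values, ts$truth_sphere | ts$truth_tube)
  })
  expect_true(all(diff(dices) <= 0.005))
})
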