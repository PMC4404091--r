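# Phantom generator: ground truth, determinism, grid hygiene.

test_that("closed-form ground truth matches the programmed solids", {
  scn <- scenario(sac_semiaxes = c(5, 5, 5), grid_shape = c(64, 64, 64),
                  seed = 3)
  truth <- scenario_truth(scn)
  expect_equal(truth$true_sac_volume_cc[["1m"]], 0.5236, tolerance = 1e-3)
  expect_equal(truth$true_delta, 0)
  expect_equal(unname(truth$true_vsg), rep(0, 4))

  g <- 1.15^(1 / 3)
  scn2 <- scenario(
    sac_semiaxes = list(`1m` = c(3, 3, 3), `1p` = c(3, 3, 3),
                        `2m` = c(3, 3, 3) * g, `2p` = c(3, 3, 3) * g),
    grid_shape = c(64, 64, 64), coil_center_offset = c(3, 4, 0) / 10)
  t2 <- scenario_truth(scn2)
  expect_equal(t2$true_delta, 0.5)
  expect_equal(t2$true_pct_vsg3, 15, tolerance = 1e-6)
})

test_that("generated volumes are deterministic and share one grid", {
  scn <- scenario(sac_semiaxes = c(2.2, 2.2, 2.2), grid_shape = c(48, 48, 48),
                  coil_center_offset = c(0.4, 0.2, 0.1), seed = 11)
  a <- make_subject(scn)
  b <- make_subject(scn)
  for (tp in names(a$timepoints)) {
    expect_identical(a$timepoints[[tp]]$subtracted$values,
                     b$timepoints[[tp]]$subtracted$values)
    expect_identical(a$timepoints[[tp]]$baseline$values,
                     b$timepoints[[tp]]$baseline$values)
    expect_identical(a$timepoints[[tp]]$subtracted$spacing,
                     a$timepoints[[tp]]$baseline$spacing)
    expect_identical(dim(a$timepoints[[tp]]$subtracted$values),
                     dim(a$timepoints[[tp]]$baseline$values))
  }
  expect_equal(a$truth$true_coil_volume_cc, b$truth$true_coil_volume_cc)
})

test_that("noiseless foreground masks agree with closed-form volumes", {
  scn <- scenario(sac_semiaxes = c(2.5, 2.5, 2.5), grid_shape = c(48, 48, 48),
                  noise_sd = 0, artifact_level = 0, seed = 5)
  subj <- make_subject(scn)
  img <- subj$timepoints[["1m"]]$subtracted
  fg <- binary_mask(img$values > 55, img$spacing, img$origin)
  # foreground = vessel + sac; sac alone bounded by closed form within one
  # surface-voxel layer
  truth_cc <- subj$truth$true_sac_volume_cc[["1m"]]
  # count voxels inside the sac ellipsoid analytically
  co <- coilwatch:::coord_arrays(dim(img$values), img$spacing, img$origin)
  ctr <- scn$sac_center[["1m"]]
  sac <- ((co$x - ctr[1]) / 2.5)^2 + ((co$y - ctr[2]) / 2.5)^2 +
    ((co$z - ctr[3]) / 2.5)^2 <= 1
  expect_true(all(sac[fg$values == FALSE] == FALSE))  # sac fully segmented
  vox_cc <- prod(img$spacing) / 1000
  layer <- surface_voxel_count(binary_mask(sac, img$spacing)) * vox_cc
  expect_lt(abs(sum(sac) * vox_cc - truth_cc), layer)
})

test_that("coil translation is programmed exactly and control subjects lack 2+", {
  scn <- scenario(sac_semiaxes = c(2.2, 2.2, 2.2), grid_shape = c(48, 48, 48),
                  coil_center_offset = c(0, 0, 0), seed = 2)
  subj <- make_subject(scn)
  expect_equal(subj$truth$true_delta, 0)
  ctrl <- scenario(sac_semiaxes = c(2.2, 2.2, 2.2),
                   grid_shape = c(48, 48, 48), control = TRUE, seed = 2)
  s2 <- make_subject(ctrl)
  expect_setequal(names(s2$timepoints), c("1m", "1p", "2m"))
  # coil centers in ground truth are ~offset apart through voxelization
  scn3 <- scenario(sac_semiaxes = c(2.5, 2.5, 2.5), grid_shape = c(48, 48, 48),
                   coil_center_offset = c(0.5, 0.3, -0.2), seed = 8)
  s3 <- make_subject(scn3)
  dc <- s3$truth$true_coil_center[["2m"]] - s3$truth$true_coil_center[["1p"]]
  expect_equal(dc, c(0.5, 0.3, -0.2), tolerance = 0.15)
})

test_that("scenarios that do not fit the grid are rejected", {
  expect_error(scenario(sac_semiaxes = c(10, 10, 10),
                        grid_shape = c(48, 48, 48)),
               "exceeds grid bounds")
  expect_error(scenario(coil_fill_fraction = 0), "coil_fill_fraction")
  expect_error(scenario(sac_semiaxes = c(-1, 2, 2)), "semi-axes")
})

test_that("cohort generation is deterministic with programmed effects", {
  expect_error(make_cohort(-1, 5), "sample sizes")
  empty <- make_cohort(0, 0, seed = 4)
  expect_length(empty$subjects, 0)

  a <- make_cohort(4, 3, seed = 9)
  b <- make_cohort(4, 3, seed = 9)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$metadata$cohort == "recurrence"), 4)
  expect_false(any(sapply(a$subjects[a$truth$cohort == "control"],
                          function(s) !s$control)))

  # programmed growth mean recovers the generating distribution
  big <- make_cohort(10, 0, seed = 21)
  m <- mean(big$truth$true_growth_pct)
  expect_lt(abs(m - 20), 3.3 * 10 / sqrt(10) + 2)  # MC error of N(20,10)
  # metadata mirrors the demographics layout
  expect_true(all(c("subject", "age", "sex", "location", "size", "ruptured",
                    "followup_months", "cohort") %in% names(a$metadata)))
  expect_no_error(coilwatch:::parse_sizes(a$metadata$size))
})

test_that("scenario YAML and NIfTI volume round trips preserve the data", {
  scn <- scenario(sac_semiaxes = c(2.2, 2.2, 2.2), grid_shape = c(48, 48, 48),
                  coil_center_offset = c(0.3, 0, 0), seed = 13)
  tmp <- tempfile(fileext = ".yaml")
  write_scenario(scn, tmp)
  scn2 <- read_scenario(tmp)
  expect_equal(scn2$sac_semiaxes, scn$sac_semiaxes)
  expect_equal(scn2$coil_center_offset, scn$coil_center_offset)
  expect_identical(make_subject(scn2)$truth$true_coil_volume_cc,
                   make_subject(scn)$truth$true_coil_volume_cc)

  subj <- make_subject(scn)
  v <- subj$timepoints[["1p"]]$baseline
  nf <- tempfile(fileext = ".nii.gz")
  write_volume(v, nf)
  v2 <- read_volume(nf, "baseline")
  expect_equal(v2$values, v$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
})
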