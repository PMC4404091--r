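# Phantom generator: paired subtracted/baseline volumes across the study
# time points (pre-first coiling 1-, post-first coiling 1+, pre-second
# coiling 2-, post-second coiling 2+) with programmed ground truth. Stands in
# for the clinical 3D rotational angiograms, which were never deposited.

# run expr under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

tp_names <- c("1m", "1p", "2m", "2p")

#' Phantom scenario
#'
#' Describes one synthetic subject: an ellipsoidal aneurysm sac on a parent
#' vessel, a coil mass built as a union of capsule segments wound along a
#' random walk confined to the sac, a programmed coil-center translation
#' between the post-first-coiling (1+) and follow-up (2-) scans, Gaussian
#' intensity noise, and a multiplicative streak artifact around the coil on
#' baseline scans. All four time points share one coordinate frame.
#'
#' @param sac_semiaxes ellipsoid semi-axes (mm): a length-3 vector used for
#'   all time points, or a named list with entries `1m`, `1p`, `2m`, `2p`.
#' @param sac_center sac center (mm): length-3 vector or per-time-point list.
#' @param vessel list with `path` (n x 3 polyline, mm) and `radius` (mm); by
#'   default a straight tube tangent to the sac running through the grid.
#' @param coil_fill_fraction target fraction of the sac volume occupied by
#'   the coil solid at 1+ and 2-, in (0, 1].
#' @param coil_wire_radius capsule radius of the wound coil segments (mm).
#' @param coil_center_offset translation (mm) of the coil solid from 1+ to
#'   2-; its Euclidean norm is the programmed delta.
#' @param residual_region blood visible on post-treatment subtracted scans:
#'   `"complement"` (default; blood fills everything in the sac the coil
#'   does not — makes the union of coil mass and residual reproduce the sac
#'   exactly, the cleanest validation geometry), `NULL` (none), or a list
#'   with `center` and `semiaxes` for an explicit ellipsoidal neck remnant.
#' @param noise_sd Gaussian intensity noise (intensity units; foreground is
#'   100, background 10).
#' @param artifact_level amplitude of the streak perturbation near the coil
#'   on baseline scans.
#' @param spacing isotropic voxel spacing, mm.
#' @param grid_shape grid size in voxels.
#' @param control logical; control subjects have no 2+ time point.
#' @param seed integer RNG seed; identical scenarios generate voxelwise
#'   identical volumes.
#' @param subject_id,cohort bookkeeping labels.
#' @return object of class `scenario`.
#' @export
scenario <- function(sac_semiaxes = c(3, 3, 3),
                     sac_center = NULL,
                     vessel = NULL,
                     coil_fill_fraction = 0.35,
                     coil_wire_radius = 0.4,
                     coil_center_offset = c(0, 0, 0),
                     residual_region = "complement",
                     noise_sd = 5,
                     artifact_level = 0.05,
                     spacing = 0.22,
                     grid_shape = c(128, 128, 128),
                     control = FALSE,
                     seed = 1L,
                     subject_id = "S01",
                     cohort = if (control) "control" else "recurrence") {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (coil_fill_fraction <= 0 || coil_fill_fraction > 1)
    stop("coil_fill_fraction must be in (0, 1]", call. = FALSE)
  extent <- (grid_shape - 1) * spacing
  center_default <- extent / 2

  if (!is.list(sac_semiaxes))
    sac_semiaxes <- setNames(rep(list(as.numeric(sac_semiaxes)), 4), tp_names)
  if (is.null(sac_center)) sac_center <- center_default
  if (!is.list(sac_center))
    sac_center <- setNames(rep(list(as.numeric(sac_center)), 4), tp_names)
  for (tp in tp_names) {
    ax <- sac_semiaxes[[tp]]
    if (is.null(ax)) next
    if (any(ax <= 0)) stop("sac semi-axes must be > 0", call. = FALSE)
    lo <- sac_center[[tp]] - ax
    hi <- sac_center[[tp]] + ax
    if (any(lo < 2 * spacing) || any(hi > extent - 2 * spacing))
      stop("solid exceeds grid bounds: sac at time point ", tp,
           " does not fit with a 2-voxel margin", call. = FALSE)
  }
  if (is.null(vessel)) {
    r <- max(sac_semiaxes[["1m"]])
    vr <- 1.2
    y0 <- sac_center[["1m"]][2] - 0.92 * (sac_semiaxes[["1m"]][2] + vr)
    vessel <- list(
      path = rbind(c(-2 * spacing[1], y0, center_default[3]),
                   c(extent[1] + 2 * spacing[1], y0, center_default[3])),
      radius = vr
    )
  }
  if (is.list(residual_region) &&
      !all(c("center", "semiaxes") %in% names(residual_region)))
    stop("residual_region list needs `center` and `semiaxes`", call. = FALSE)

  structure(
    list(sac_semiaxes = sac_semiaxes, sac_center = sac_center,
         vessel = vessel, coil_fill_fraction = coil_fill_fraction,
         coil_wire_radius = coil_wire_radius,
         coil_center_offset = as.numeric(coil_center_offset),
         residual_region = residual_region, noise_sd = noise_sd,
         artifact_level = artifact_level, spacing = spacing,
         grid_shape = grid_shape, control = isTRUE(control),
         seed = as.integer(seed), subject_id = subject_id, cohort = cohort),
    class = "scenario"
  )
}

ellipsoid_volume_cc <- function(semiaxes) 4 / 3 * pi * prod(semiaxes) / 1000

ellipsoid_mask <- function(co, center, semiaxes) {
  ((co$x - center[1]) / semiaxes[1])^2 +
    ((co$y - center[2]) / semiaxes[2])^2 +
    ((co$z - center[3]) / semiaxes[3])^2 <= 1
}

# union of capsules along a polyline, computed segment-wise in bounding boxes
capsule_mask <- function(co, dims, spacing, origin, pts, radius) {
  m <- array(FALSE, dims)
  radius <- rep_len(radius, max(1, nrow(pts) - 1))
  for (i in seq_len(nrow(pts) - 1)) {
    p <- pts[i, ]; q <- pts[i + 1, ]; r <- radius[i]
    lo <- point_to_voxel(pmin(p, q) - r - spacing, spacing, origin, dims)
    hi <- point_to_voxel(pmax(p, q) + r + spacing, spacing, origin, dims)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx <- co$x[xs, ys, zs] - p[1]
    dy <- co$y[xs, ys, zs] - p[2]
    dz <- co$z[xs, ys, zs] - p[3]
    v <- q - p
    vv <- sum(v^2)
    t <- if (vv > 0) pmin(pmax((dx * v[1] + dy * v[2] + dz * v[3]) / vv, 0), 1)
         else 0
    d2 <- (dx - t * v[1])^2 + (dy - t * v[2])^2 + (dz - t * v[3])^2
    m[xs, ys, zs] <- m[xs, ys, zs] | (d2 <= r^2)
  }
  m
}

# random walk of capsule segments confined to an ellipsoidal region; grown
# until the coil occupies `fill_fraction` of `sac_voxels` voxels (or the
# walk budget is exhausted). Returns the polyline; voxelization is separate
# so the same path can be translated and re-voxelized exactly.
coil_walk <- function(region_center, region_semiaxes, wire_radius, step = 1.2,
                      max_segments = 600L) {
  region_semiaxes <- pmax(region_semiaxes, 0.3)
  step <- min(step, 0.6 * min(region_semiaxes))
  inside <- function(p)
    sum(((p - region_center) / region_semiaxes)^2) <= 1
  pts <- matrix(region_center, nrow = 1)
  p <- region_center
  for (s in seq_len(max_segments)) {
    for (try in 1:20) {
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2))
      cand <- p + step * d
      if (inside(cand)) break
      cand <- NULL
    }
    if (is.null(cand)) cand <- region_center  # fall back toward the center
    pts <- rbind(pts, cand)
    p <- cand
  }
  pts
}

norm3 <- function(v) sqrt(sum(v^2))

#' Closed-form ground truth of a scenario
#'
#' Sac volumes (ellipsoid closed form), programmed coil translation and the
#' sac-growth differences under all four definitions, available without
#' voxelizing anything. [make_subject()] augments this with the voxel-count
#' coil volumes and centers of the generated coil solid.
#'
#' @param scn a [scenario()].
#' @return list of class `ground_truth`.
#' @export
scenario_truth <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  tps <- if (scn$control) tp_names[1:3] else tp_names
  vs <- sapply(tp_names, function(tp)
    if (tp %in% tps) ellipsoid_volume_cc(scn$sac_semiaxes[[tp]]) else NA_real_)
  vsg <- c(vsg1 = vs[["2p"]] - vs[["1m"]], vsg2 = vs[["2p"]] - vs[["1p"]],
           vsg3 = vs[["2m"]] - vs[["1m"]], vsg4 = vs[["2m"]] - vs[["1p"]])
  structure(
    list(true_sac_volume_cc = vs,
         true_coil_volume_cc = c(`1p` = NA_real_, `2m` = NA_real_),
         true_coil_center = NULL,
         true_delta = norm3(scn$coil_center_offset),
         true_vsg = vsg,
         true_pct_vsg3 = 100 * vsg[["vsg3"]] / vs[["1m"]]),
    class = "ground_truth"
  )
}

#' Generate the paired subtracted/baseline volumes of one phantom subject
#'
#' Subtracted volumes contain the vessel plus the sac (1-) or the vessel plus
#' residual blood (1+, 2-, 2+) as bright foreground over a dark background
#' with additive Gaussian noise. Baseline volumes contain the coil solid with
#' noise and a multiplicative streak artifact; the 1- baseline holds no coil
#' (nothing radio-dense in a cropped field of view pre-treatment). The coil
#' at 2- is the 1+ coil path translated by the programmed offset and
#' re-voxelized; recurrence subjects get a fresh coil at 2+. Identical
#' scenarios (including seed) generate voxelwise identical output.
#'
#' @param scn a [scenario()].
#' @return list with `timepoints` (per time point, `subtracted` and
#'   `baseline` [image_volume()]s), `truth` (`ground_truth`), `seeds`
#'   (suggested seed points, mm: `sac` per time point and `vessel`), and the
#'   `scenario`.
#' @export
make_subject <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  with_seed(scn$seed, make_subject_impl(scn))
}

make_subject_impl <- function(scn) {
  dims <- scn$grid_shape
  sp <- scn$spacing
  origin <- c(0, 0, 0)
  co <- coord_arrays(dims, sp, origin)
  tps <- if (scn$control) tp_names[1:3] else tp_names

  vessel <- capsule_mask(co, dims, sp, origin, scn$vessel$path,
                         scn$vessel$radius)
  sacs <- lapply(tp_names, function(tp)
    ellipsoid_mask(co, scn$sac_center[[tp]], scn$sac_semiaxes[[tp]]))
  names(sacs) <- tp_names

  # coil at 1+: random walk confined to an ellipsoidal core of the sac,
  # recessed so the translated coil at 2- still fits inside the grown sac
  off <- scn$coil_center_offset
  ax1 <- scn$sac_semiaxes[["1p"]]
  enorm <- norm3(off / ax1)
  s_core <- max(0.25, 1 - 0.15 - 0.5 * enorm)
  c1 <- scn$sac_center[["1p"]] - off / 2
  sac_vox <- sum(sacs[["1p"]])
  target <- scn$coil_fill_fraction * sac_vox

  path1 <- coil_walk(c1, s_core * ax1 - scn$coil_wire_radius,
                     scn$coil_wire_radius)
  coil1 <- array(FALSE, dims)
  n_seg <- 0L
  repeat {
    n_seg <- n_seg + 1L
    if (n_seg >= nrow(path1)) break
    seg <- path1[n_seg:(n_seg + 1), , drop = FALSE]
    coil1 <- coil1 | capsule_mask(co, dims, sp, origin, seg,
                                  scn$coil_wire_radius)
    if (sum(coil1) >= target) break
  }
  path_used <- path1[seq_len(min(n_seg + 1L, nrow(path1))), , drop = FALSE]
  path2 <- sweep(path_used, 2, off, `+`)
  coil2 <- capsule_mask(co, dims, sp, origin, path2, scn$coil_wire_radius)

  coil2p <- NULL
  if (!scn$control) {
    # wound with the same core confinement as the 1+ coil so that the
    # post-treatment sac geometry is comparable across time points and
    # longitudinal volume differences reflect programmed growth only
    ax2p <- scn$sac_semiaxes[["2p"]]
    path2p <- coil_walk(scn$sac_center[["2p"]],
                        s_core * ax2p - scn$coil_wire_radius,
                        scn$coil_wire_radius)
    coil2p <- array(FALSE, dims)
    t2p <- scn$coil_fill_fraction * sum(sacs[["2p"]])
    k <- 0L
    repeat {
      k <- k + 1L
      if (k >= nrow(path2p)) break
      coil2p <- coil2p | capsule_mask(co, dims, sp, origin,
                                      path2p[k:(k + 1), , drop = FALSE],
                                      scn$coil_wire_radius)
      if (sum(coil2p) >= t2p) break
    }
  }
  coils <- list(`1m` = NULL, `1p` = coil1, `2m` = coil2, `2p` = coil2p)

  residual_for <- function(tp) {
    if (is.null(scn$residual_region)) return(array(FALSE, dims))
    if (identical(scn$residual_region, "complement"))
      return(sacs[[tp]] & !coils[[tp]])
    ellipsoid_mask(co, scn$residual_region$center,
                   scn$residual_region$semiaxes)
  }

  bg <- 10; fg_gain <- 90
  render <- function(fgmask, modality, artifact_center = NULL) {
    img <- bg + fg_gain * fgmask + rnorm(prod(dims), 0, scn$noise_sd)
    dim(img) <- dims
    if (!is.null(artifact_center) && scn$artifact_level > 0) {
      dx <- co$x - artifact_center[1]
      dy <- co$y - artifact_center[2]
      rr <- sqrt(dx^2 + dy^2 + (co$z - artifact_center[3])^2)
      streak <- sin(8 * atan2(dy, dx))^2 * exp(-rr / 4)
      img <- img * (1 + scn$artifact_level * streak)
    }
    image_volume(img, sp, origin, modality)
  }

  volumes <- list()
  for (tp in tps) {
    fg_sub <- if (tp == "1m") vessel | sacs[["1m"]] else vessel | residual_for(tp)
    coil <- coils[[tp]]
    art_center <- if (!is.null(coil) && any(coil))
      c(mean(co$x[coil]), mean(co$y[coil]), mean(co$z[coil])) else NULL
    volumes[[tp]] <- list(
      subtracted = render(fg_sub, "subtracted"),
      baseline = render(if (is.null(coil)) array(FALSE, dims) else coil,
                        "baseline", art_center)
    )
  }

  truth <- scenario_truth(scn)
  vc <- voxel_cc(sp)
  truth$true_coil_volume_cc <- c(`1p` = sum(coil1) * vc, `2m` = sum(coil2) * vc)
  ctr <- function(m) c(mean(co$x[m]), mean(co$y[m]), mean(co$z[m]))
  truth$true_coil_center <- list(`1p` = ctr(coil1), `2m` = ctr(coil2))

  vessel_mid <- resample_polyline(scn$vessel$path, 0.5)
  grid_center <- (dims - 1) * sp / 2
  vd <- sqrt(rowSums(sweep(vessel_mid, 2, grid_center, `-`)^2))
  # user-style VOI annotation: a generous box around the aneurysm, within
  # which intensity thresholds are estimated (the foreground fraction there
  # is large enough for Otsu's bimodality assumption)
  ax_max <- apply(do.call(rbind, scn$sac_semiaxes[
    if (scn$control) tp_names[1:3] else tp_names]), 2, max)
  voi <- list(min = scn$sac_center[["1m"]] - ax_max - 2,
              max = scn$sac_center[["1m"]] + ax_max + 2)
  list(
    timepoints = volumes,
    truth = truth,
    seeds = list(
      sac = scn$sac_center,
      vessel = vessel_mid[which.min(vd), ],
      voi = voi
    ),
    scenario = scn
  )
}

#' Effect parameters for a synthetic cohort
#'
#' Defaults encode the study conditions used throughout: recurrence subjects
#' with mean +20 percent sac volume growth and 2 mm coil-center translation,
#' controls with zero mean growth and 0.5 mm incidental translation, zero
#' programmed coil-volume change in both cohorts.
#'
#' @param growth_pct_mean,growth_pct_sd recurrence sac growth, percent of
#'   initial volume.
#' @param control_growth_sd control growth jitter (percent, mean zero).
#' @param delta_mean_recurrence,delta_sd_recurrence coil translation (mm).
#' @param delta_mean_control,delta_sd_control control translation (mm).
#' @param sac_radius_range range of mean sac semi-axis (mm).
#' @param coil_fill_fraction target coil fill fraction of the sac.
#' @param noise_sd,artifact_level image noise and artifact amplitude.
#' @param spacing,grid_shape phantom grid geometry (a cropped 0.22 mm
#'   volume of interest around the aneurysm).
#' @return named list of parameters.
#' @export
cohort_effects <- function(growth_pct_mean = 20, growth_pct_sd = 10,
                           control_growth_sd = 2,
                           delta_mean_recurrence = 2.0,
                           delta_sd_recurrence = 0.5,
                           delta_mean_control = 0.5,
                           delta_sd_control = 0.2,
                           sac_radius_range = c(2.6, 3.6),
                           coil_fill_fraction = 0.35,
                           noise_sd = 5, artifact_level = 0.05,
                           spacing = 0.22, grid_shape = c(72, 72, 72)) {
  as.list(environment())
}

#' Generate a synthetic cohort of scenarios plus a metadata table
#'
#' Recurrence subjects are drawn with positive mean sac growth and larger
#' coil translation; controls with near-zero growth and small translation.
#' Subjects are returned as [scenario()] objects (materialize any of them
#' with [make_subject()]); the metadata table mirrors the study's
#' demographics layout (subject, age, sex, location, size HxW, rupture
#' status, follow-up).
#'
#' @param n_recurrence,n_control subject counts (>= 0).
#' @param effect_params see [cohort_effects()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with `subjects` (list of scenarios), `metadata`
#'   (data.frame) and `truth` (data.frame of programmed per-subject effects).
#' @export
make_cohort <- function(n_recurrence = 15L, n_control = 12L,
                        effect_params = cohort_effects(), seed = 1L) {
  if (n_recurrence < 0 || n_control < 0)
    stop("sample sizes must be >= 0", call. = FALSE)
  ep <- utils::modifyList(cohort_effects(), effect_params)
  n <- n_recurrence + n_control
  if (n == 0)
    return(list(subjects = list(),
                metadata = data.frame(), truth = data.frame()))
  with_seed(seed, {
    cohort <- c(rep("recurrence", n_recurrence), rep("control", n_control))
    r_mean <- runif(n, ep$sac_radius_range[1], ep$sac_radius_range[2])
    anis <- matrix(runif(2 * n, 0.85, 1.05), ncol = 2)
    growth <- ifelse(
      cohort == "recurrence",
      pmax(rnorm(n, ep$growth_pct_mean, ep$growth_pct_sd), 2),
      rnorm(n, 0, ep$control_growth_sd)
    )
    dmag <- ifelse(
      cohort == "recurrence",
      pmax(rnorm(n, ep$delta_mean_recurrence, ep$delta_sd_recurrence), 0.2),
      pmax(rnorm(n, ep$delta_mean_control, ep$delta_sd_control), 0.05)
    )
    ddir <- matrix(rnorm(3 * n), ncol = 3)
    ddir <- ddir / sqrt(rowSums(ddir^2))
    age <- pmin(pmax(round(rnorm(n, 53, 12)), 16), 85)
    sex <- ifelse(runif(n) < 0.8, "F", "M")
    loc <- sample(c("Acom", "Basilar tip", "L MCA", "R pcom", "L ICA",
                    "R ICA", "L paraophthalmic"), n, replace = TRUE)
    rupt <- ifelse(runif(n) < 0.4, "Ruptured", "Unruptured")
    fup <- round(runif(n, 2, 24), 1)
    subj_seed <- abs(seed %% 100000L) * 1000L + seq_len(n)

    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      ax1 <- r_mean[i] * c(1, anis[i, 1], anis[i, 2])
      scale2 <- (1 + growth[i] / 100)^(1 / 3)
      grid <- rep_len(ep$grid_shape, 3)
      ext <- (grid - 1) * ep$spacing
      ctr <- ext / 2
      subjects[[i]] <- scenario(
        sac_semiaxes = list(`1m` = ax1, `1p` = ax1,
                            `2m` = ax1 * scale2, `2p` = ax1 * scale2),
        sac_center = ctr,
        coil_fill_fraction = ep$coil_fill_fraction,
        coil_center_offset = dmag[i] * ddir[i, ],
        noise_sd = ep$noise_sd, artifact_level = ep$artifact_level,
        spacing = ep$spacing, grid_shape = grid,
        control = cohort[i] == "control",
        seed = subj_seed[i],
        subject_id = sprintf("P%02d", i),
        cohort = cohort[i]
      )
    }
    metadata <- data.frame(
      subject = sprintf("P%02d", seq_len(n)),
      age = age, sex = sex, location = loc,
      size = paste0(round(2 * r_mean * pmax(1, anis[, 1])), "x",
                    round(2 * r_mean * pmin(1, anis[, 2]))),
      ruptured = rupt, followup_months = fup, cohort = cohort,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      subject = metadata$subject, cohort = cohort,
      true_growth_pct = growth, true_delta_mm = dmag,
      true_vs1m_cc = sapply(subjects, function(s)
        ellipsoid_volume_cc(s$sac_semiaxes[["1m"]])),
      stringsAsFactors = FALSE
    )
    list(subjects = subjects, metadata = metadata, truth = truth)
  })
}

#' Write a scenario to / read it from YAML
#'
#' @param scn a [scenario()]; `path` a file path.
#' @return `read_scenario` returns a [scenario()].
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  x <- unclass(scn)
  x$vessel$path <- lapply(seq_len(nrow(x$vessel$path)),
                          function(i) as.numeric(x$vessel$path[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  x$vessel$path <- do.call(rbind, lapply(x$vessel$path, as.numeric))
  for (f in c("sac_semiaxes", "sac_center"))
    x[[f]] <- lapply(x[[f]], as.numeric)
  do.call(scenario, x)
}
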