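# Study orchestration: the per-subject measurement chain over the four time
# points, cohort-level statistics, demographics, and the investigator
# sensitivity comparison.

default_seg_params <- function() {
  list(open_radius = 1L, close_radius = 1L,
       levelset = levelset_params(), fill_connectivity = 6L)
}

default_geom_params <- function() {
  list(tube_scale = 1.1, radius_cap_factor = 1.5, smooth_sigma = 0.5)
}

#' Measure one subject across its available time points
#'
#' Runs the full measurement chain. At 1- the sac is still open: the
#' vascular segmentation of the subtracted scan is meshed and the sac
#' isolated directly. At 1+, 2- and 2+ the sac is no longer angiographically
#' visible: the coil mass is segmented from the baseline scan, the vessels
#' and residual blood from the subtracted scan, and the sac is isolated from
#' their Boolean union. Coil volumes and centers are measured on the coil
#' mesh at 1+ and 2-. A missing scan leaves the corresponding volume NA; a
#' segmentation failure at one time point is recorded and the subject
#' continues.
#'
#' @param subject output of [make_subject()], or an equivalent list with
#'   `timepoints` (per time point `subtracted`/`baseline` volumes), `seeds`
#'   (`sac` per time point, `vessel`), and `scenario` carrying `subject_id`
#'   and `cohort`.
#' @param seg segmentation parameters; see defaults in the source.
#' @param geom geometry parameters passed to [isolate_sac()].
#' @param seed_offset optional mm offset added to every seed point (used by
#'   the investigator-sensitivity study: a second user places seeds
#'   elsewhere inside the same structures).
#' @return A [subject_volumes()] with attribute `status` (per-time-point
#'   message, "ok" when clean).
#' @export
run_subject <- function(subject, seg = list(), geom = list(),
                        seed_offset = c(0, 0, 0)) {
  seg <- utils::modifyList(default_seg_params(), seg)
  geom <- utils::modifyList(default_geom_params(), geom)
  tps <- names(subject$timepoints)
  if (!any(c("1m", "1p") %in% tps) || !any(c("2m", "2p") %in% tps))
    stop("cannot compute any growth definition; missing time points: ",
         paste(setdiff(tp_names, tps), collapse = ", "), call. = FALSE)
  scn <- subject$scenario
  status <- setNames(rep("ok", length(tps)), tps)
  vols <- list(vs1m = NA_real_, vs1p = NA_real_, vs2m = NA_real_,
               vs2p = NA_real_, vc1p = NA_real_, vc2m = NA_real_)
  cents <- list(c1p = NULL, c2m = NULL)

  iso_args <- function(mask, seed) {
    isolate_sac(mask, seed, tube_scale = geom$tube_scale,
                radius_cap_factor = geom$radius_cap_factor,
                smooth_sigma = geom$smooth_sigma)
  }

  for (tp in intersect(tp_names, tps)) {
    entry <- subject$timepoints[[tp]]
    sac_seed <- subject$seeds$sac[[tp]] + seed_offset
    res <- tryCatch({
      voi <- subject$seeds$voi
      if (tp == "1m") {
        angio <- segment_vascular(entry$subtracted, sac_seed, voi = voi,
                                  open_radius = seg$open_radius,
                                  levelset = seg$levelset)
        sm <- iso_args(angio, sac_seed)
        vols$vs1m <- sm$volume_cc
      } else {
        coil <- segment_coil(entry$baseline, close_radius = seg$close_radius,
                             voi = voi, levelset = seg$levelset,
                             fill_connectivity = seg$fill_connectivity)
        vseed <- subject$seeds$vessel + seed_offset
        angio <- segment_vascular(entry$subtracted, vseed, voi = voi,
                                  open_radius = seg$open_radius,
                                  levelset = seg$levelset)
        # the sac seed is clicked on the coil mass (always inside the union)
        sac_seed_eff <- snap_to_mask(coil, sac_seed)
        sm <- build_posttreatment_sac(coil, angio, sac_seed_eff,
                                      tube_scale = geom$tube_scale,
                                      radius_cap_factor = geom$radius_cap_factor,
                                      smooth_sigma = geom$smooth_sigma)
        key <- paste0("vs", tp)
        vols[[key]] <- sm$volume_cc
        if (tp %in% c("1p", "2m")) {
          cm <- extract_surface(coil, geom$smooth_sigma)
          vols[[paste0("vc", tp)]] <- mesh_volume(cm)
          cents[[paste0("c", tp)]] <- mesh_centroid(cm)
        }
      }
      "ok"
    }, error = function(e) conditionMessage(e))
    status[tp] <- res
  }

  sv <- subject_volumes(
    subject_id = scn$subject_id, cohort = scn$cohort,
    vs1m = vols$vs1m, vs1p = vols$vs1p, vs2m = vols$vs2m, vs2p = vols$vs2p,
    vc1p = vols$vc1p, vc2m = vols$vc2m,
    c1p = cents$c1p, c2m = cents$c2m
  )
  attr(sv, "status") <- status
  sv
}

#' Run the full synthetic study
#'
#' Materializes each scenario, measures it with [run_subject()], and runs
#' the study-level analysis: per-subject metrics, the per-definition cohort
#' summaries, the between-cohort one-tailed Mann-Whitney comparison of the
#' coil-center translation delta, an ROC for delta (and for clinically
#' measured sac size when metadata provides sizes), and min/median/max
#' reporting per cohort.
#'
#' @param cohort output of [make_cohort()] (or a list with `subjects` as
#'   scenarios and optional `metadata`).
#' @param seg,geom parameter lists, as in [run_subject()].
#' @param verbose print per-subject progress.
#' @return list of class `study_result`: `results` (per-subject data.frame),
#'   `summaries`, `delta_test`, `roc_delta`, `roc_size`, `ranges`, `status`.
#' @export
run_study <- function(cohort, seg = list(), geom = list(), verbose = FALSE) {
  subjects <- cohort$subjects
  if (length(subjects) == 0) stop("no subjects", call. = FALSE)
  rows <- vector("list", length(subjects))
  status <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    scn <- subjects[[i]]
    subj <- make_subject(scn)
    sv <- run_subject(subj, seg = seg, geom = geom)
    rows[[i]] <- growth_result(sv)
    status[[i]] <- attr(sv, "status")
    if (verbose)
      message(scn$subject_id, " (", scn$cohort, "): vsg def ",
              rows[[i]]$vsg_definition, ", pct ",
              round(rows[[i]]$pct_vsg, 1))
    rm(subj)
  }
  results <- do.call(rbind, rows)
  names(status) <- results$subject_id

  cohorts <- unique(results$cohort)
  summaries <- do.call(rbind, lapply(cohorts, function(ch)
    summarize_cohort(results, ch)))

  delta_test <- NULL
  roc_delta <- NULL
  if (all(c("recurrence", "control") %in% cohorts)) {
    dr <- results$delta[results$cohort == "recurrence"]
    dc <- results$delta[results$cohort == "control"]
    dr <- dr[!is.na(dr)]; dc <- dc[!is.na(dc)]
    if (length(dr) > 0 && length(dc) > 0) {
      delta_test <- mann_whitney_one_tailed(dr, dc, "greater")
      roc_delta <- roc(results$delta, results$cohort == "recurrence")
    }
  }

  roc_size <- NULL
  md <- cohort$metadata
  if (!is.null(md) && nrow(md) > 0 && "size" %in% names(md) &&
      length(unique(md$cohort)) == 2) {
    sz <- parse_sizes(md$size)
    roc_size <- roc(clinical_size(sz$h, sz$w), md$cohort == "recurrence")
  }

  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(min = NA, median = NA, max = NA))
    c(min = min(v), median = median(v), max = max(v))
  }
  ranges <- do.call(rbind, lapply(cohorts, function(ch) {
    r <- results[results$cohort == ch, ]
    data.frame(cohort = ch,
               rbind(vsg = rng(r$vsg), vcg = rng(r$vcg),
                     delta = rng(r$delta)),
               quantity = c("vsg", "vcg", "delta"))
  }))

  structure(
    list(results = results, summaries = summaries, delta_test = delta_test,
         roc_delta = roc_delta, roc_size = roc_size, ranges = ranges,
         status = status),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", nrow(x$results), " subjects\n", sep = "")
  print(x$summaries, row.names = FALSE)
  if (!is.null(x$delta_test))
    cat("delta Mann-Whitney one-tailed p =",
        signif(x$delta_test$p_value, 3), "\n")
  if (!is.null(x$roc_delta))
    cat("delta ROC AUC =", signif(x$roc_delta$auc, 3),
        ", optimal cutoff =", signif(x$roc_delta$optimal_threshold, 3),
        "mm\n")
  invisible(x)
}

parse_sizes <- function(size) {
  parts <- strsplit(trimws(size), "[xX]")
  bad <- vapply(parts, function(p) length(p) != 2 ||
                  anyNA(suppressWarnings(as.numeric(p))), logical(1))
  if (any(bad))
    stop("malformed size strings: ",
         paste(size[bad], collapse = ", "), call. = FALSE)
  h <- vapply(parts, function(p) as.numeric(p)[1], numeric(1))
  w <- vapply(parts, function(p) as.numeric(p)[2], numeric(1))
  list(h = h, w = w)
}

#' The packaged study demographics table
#'
#' Subject-level procedural and demographic information of the 15 recurrence
#' and 12 control aneurysms: age, sex, location, angiographic size
#' (height x width, mm), rupture status and follow-up interval (months).
#'
#' @return data.frame with one row per aneurysm.
#' @export
read_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "coilwatch")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Demographics summary of a cohort table
#'
#' Computes, per cohort: the number of aneurysms, the clinically measured
#' sac sizes (largest of height and width), their median, the count of
#' aneurysms 10 mm or larger, the mean follow-up per aneurysm and per
#' patient (rows sharing age, sex and follow-up interval are one patient
#' with multiple aneurysms), plus a two-sided Mann-Whitney comparison of
#' sizes between cohorts.
#'
#' @param table data.frame with columns `cohort`, `age`, `sex`, `size`
#'   (strings like `"26x17"`), `followup_months`.
#' @return list: `per_cohort` (data.frame), `size_test` (two-sided
#'   Mann-Whitney p-value and U), `sizes` (per-subject clinical sizes).
#' @export
demographics_summary <- function(table) {
  sz <- parse_sizes(table$size)
  csize <- clinical_size(sz$h, sz$w)
  per <- do.call(rbind, lapply(unique(table$cohort), function(ch) {
    t <- table[table$cohort == ch, ]
    s <- csize[table$cohort == ch]
    pat <- !duplicated(paste(t$age, t$sex, t$followup_months))
    data.frame(
      cohort = ch,
      n_aneurysms = nrow(t),
      n_patients = sum(pat),
      median_size_mm = median(s),
      n_size_ge_10mm = sum(s >= 10),
      mean_followup_aneurysm = mean(t$followup_months),
      mean_followup_patient = mean(t$followup_months[pat]),
      stringsAsFactors = FALSE
    )
  }))
  size_test <- NULL
  chs <- unique(table$cohort)
  if (length(chs) == 2) {
    a <- csize[table$cohort == chs[1]]
    b <- csize[table$cohort == chs[2]]
    pg <- mann_whitney_one_tailed(a, b, "greater")
    pl <- mann_whitney_one_tailed(a, b, "less")
    size_test <- list(U = pg$U,
                      p_value = min(1, 2 * min(pg$p_value, pl$p_value)))
  }
  list(per_cohort = per, size_test = size_test,
       sizes = data.frame(cohort = table$cohort, size_mm = csize))
}

#' Investigator sensitivity comparison
#'
#' Pairs the sac and coil volumes measured in two analysis runs (e.g. two
#' blinded investigators placing their own seed points) over the common
#' subjects, and reports the coefficient of determination for each.
#'
#' @param runA,runB data.frames of per-subject rows (as from
#'   [growth_result()]), containing subject_id, the sac volumes
#'   `vs1m..vs2p` and coil volumes `vc1p`, `vc2m`.
#' @return list: `r2_sac`, `r2_coil`, `pairs` (the paired long-format data).
#' @export
compare_investigators <- function(runA, runB) {
  common <- intersect(runA$subject_id, runB$subject_id)
  if (length(common) == 0)
    stop("no overlapping subjects between the two runs", call. = FALSE)
  a <- runA[match(common, runA$subject_id), ]
  b <- runB[match(common, runB$subject_id), ]
  sac_cols <- c("vs1m", "vs1p", "vs2m", "vs2p")
  coil_cols <- c("vc1p", "vc2m")
  long <- function(cols) {
    va <- unlist(a[cols], use.names = FALSE)
    vb <- unlist(b[cols], use.names = FALSE)
    keep <- !is.na(va) & !is.na(vb)
    data.frame(a = va[keep], b = vb[keep])
  }
  sac <- long(sac_cols)
  coil <- long(coil_cols)
  list(
    r2_sac = r_squared(sac$a, sac$b),
    r2_coil = if (nrow(coil) >= 2) r_squared(coil$a, coil$b) else NA_real_,
    pairs = list(sac = sac, coil = coil)
  )
}

#' Write per-subject results to CSV
#'
#' @param results per-subject data.frame (from `run_study()$results`).
#' @param path output path.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
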