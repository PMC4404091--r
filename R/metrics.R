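# Per-subject growth and translation quantities. Availability is explicit:
# a missing volume is NA, never zero — the retrospective design means some
# scans (especially baselines) were never recorded, and the per-definition
# sample sizes must reproduce that bookkeeping.

#' Measured volumes and coil centers of one subject
#'
#' @param subject_id identifier.
#' @param cohort `"recurrence"` or `"control"`.
#' @param vs1m,vs1p,vs2m,vs2p sac volumes (cc) at 1-, 1+, 2-, 2+; NA when
#'   the scan is unavailable. Control subjects have no 2+ scan.
#' @param vc1p,vc2m coil-mass volumes (cc) at 1+ and 2-.
#' @param c1p,c2m coil-mass centers (mm, length 3) at 1+ and 2-; must be
#'   present exactly when the corresponding coil volume is.
#' @return object of class `subject_volumes`.
#' @export
subject_volumes <- function(subject_id, cohort = c("recurrence", "control"),
                            vs1m = NA, vs1p = NA, vs2m = NA, vs2p = NA,
                            vc1p = NA, vc2m = NA, c1p = NULL, c2m = NULL) {
  cohort <- match.arg(cohort)
  vols <- c(vs1m = vs1m, vs1p = vs1p, vs2m = vs2m, vs2p = vs2p,
            vc1p = vc1p, vc2m = vc2m)
  if (any(!is.na(vols) & vols <= 0))
    stop("volumes must be positive when present", call. = FALSE)
  if (cohort == "control" && !is.na(vs2p))
    stop("control subjects have no 2+ time point", call. = FALSE)
  if (!is.na(vc1p) && is.null(c1p))
    stop("coil centroid c1p required when vc1p is present", call. = FALSE)
  if (!is.na(vc2m) && is.null(c2m))
    stop("coil centroid c2m required when vc2m is present", call. = FALSE)
  structure(
    list(subject_id = subject_id, cohort = cohort,
         vs1m = vs1m, vs1p = vs1p, vs2m = vs2m, vs2p = vs2p,
         vc1p = vc1p, vc2m = vc2m, c1p = c1p, c2m = c2m),
    class = "subject_volumes"
  )
}

#' Volumetric sac growth under the prioritized definitions
#'
#' Sac growth is the difference in sac volume between follow-up and initial
#' presentation; positive values indicate growth. Two volumes exist at each
#' presentation (pre/post treatment), giving four definitions:
#' `VSG1 = VS2+ - VS1-`, `VSG2 = VS2+ - VS1+`, `VSG3 = VS2- - VS1-`,
#' `VSG4 = VS2- - VS1+`. The highest-priority computable definition (in the
#' order 1, 2, 3, 4) is returned. Controls lack the 2+ scan, so definitions
#' 1 and 2 are never computable for them.
#'
#' @param sv a [subject_volumes()].
#' @return list with `vsg` (cc) and `definition` (1-4).
#' @export
compute_vsg <- function(sv) {
  stopifnot(inherits(sv, "subject_volumes"))
  defs <- list(
    list(def = 1L, a = sv$vs2p, b = sv$vs1m),
    list(def = 2L, a = sv$vs2p, b = sv$vs1p),
    list(def = 3L, a = sv$vs2m, b = sv$vs1m),
    list(def = 4L, a = sv$vs2m, b = sv$vs1p)
  )
  for (d in defs) {
    if (!is.na(d$a) && !is.na(d$b))
      return(list(vsg = d$a - d$b, definition = d$def))
  }
  missing <- names(which(is.na(c(vs1m = sv$vs1m, vs1p = sv$vs1p,
                                 vs2m = sv$vs2m, vs2p = sv$vs2p))))
  stop("no sac-growth definition computable; missing volumes: ",
       paste(missing, collapse = ", "), call. = FALSE)
}

#' Percent sac growth
#'
#' The denominator is the initial volume entering the definition used:
#' `VS1-` for definitions 1 and 3, `VS1+` for definitions 2 and 4.
#'
#' @param sv a [subject_volumes()].
#' @param vsg,definition output of [compute_vsg()].
#' @return percent growth.
#' @export
compute_pct_vsg <- function(sv, vsg, definition) {
  denom <- if (definition %in% c(1L, 3L)) sv$vs1m else sv$vs1p
  if (is.na(denom)) stop("initial volume for definition ", definition,
                         " unavailable", call. = FALSE)
  if (denom == 0) stop("zero initial volume", call. = FALSE)
  100 * vsg / denom
}

#' Volumetric coil-mass growth
#'
#' `VCG = VC2- - VC1+`; negative values indicate compaction. Percent change
#' is relative to the initial coil volume. Unavailable (NA) when either coil
#' volume is missing — in the retrospective data this was the common case.
#'
#' @param sv a [subject_volumes()].
#' @return list with `vcg` (cc) and `pct_vcg` (percent), both NA when not
#'   computable.
#' @export
compute_vcg <- function(sv) {
  stopifnot(inherits(sv, "subject_volumes"))
  if (is.na(sv$vc1p) || is.na(sv$vc2m))
    return(list(vcg = NA_real_, pct_vcg = NA_real_))
  vcg <- sv$vc2m - sv$vc1p
  list(vcg = vcg, pct_vcg = 100 * vcg / sv$vc1p)
}

#' Translation of the coil-mass center
#'
#' Euclidean distance between the coil-mass centers at the initial (1+) and
#' follow-up (2-) time points, both expressed in one coordinate frame.
#'
#' @param c1p,c2m length-3 points (mm); either may be NULL/NA (unavailable).
#' @return distance in mm, or NA when a centroid is missing.
#' @export
compute_delta <- function(c1p, c2m) {
  if (is.null(c1p) || is.null(c2m) || anyNA(c1p) || anyNA(c2m))
    return(NA_real_)
  sqrt(sum((as.numeric(c1p) - as.numeric(c2m))^2))
}

#' Clinically measured sac size
#'
#' The larger of the height and width read off the angiogram.
#'
#' @param height_mm,width_mm positive sizes in mm (vectorized).
#' @return pairwise maximum, mm.
#' @export
clinical_size <- function(height_mm, width_mm) {
  if (any(height_mm <= 0) || any(width_mm <= 0))
    stop("sizes must be positive", call. = FALSE)
  pmax(height_mm, width_mm)
}

#' Growth/translation summary of one subject
#'
#' Applies [compute_vsg()], [compute_pct_vsg()], [compute_vcg()] and
#' [compute_delta()] and returns one tidy row.
#'
#' @param sv a [subject_volumes()].
#' @return one-row data.frame: subject_id, cohort, the six volumes, vsg,
#'   vsg_definition, pct_vsg, vcg, pct_vcg, delta.
#' @export
growth_result <- function(sv) {
  g <- compute_vsg(sv)
  pct <- compute_pct_vsg(sv, g$vsg, g$definition)
  cg <- compute_vcg(sv)
  data.frame(
    subject_id = sv$subject_id, cohort = sv$cohort,
    vs1m = sv$vs1m, vs1p = sv$vs1p, vs2m = sv$vs2m, vs2p = sv$vs2p,
    vc1p = sv$vc1p, vc2m = sv$vc2m,
    vsg = g$vsg, vsg_definition = g$definition, pct_vsg = pct,
    vcg = cg$vcg, pct_vcg = cg$pct_vcg,
    delta = compute_delta(sv$c1p, sv$c2m),
    stringsAsFactors = FALSE
  )
}
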