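#' Rigid-body observation
#'
#' One rigid body (bone or prosthesis) as seen in one examination: labeled
#' 3D marker positions used for fitting, plus optional *fictive points* --
#' virtual feature points (e.g. the stem tip, baseplate corners) attached to
#' the body whose motion is reported but which do not enter the rigid fit.
#'
#' @param markers n x 3 matrix (rownames = marker ids) or data.frame with
#'   `marker_id`, `x`, `y`, `z`; at least 3 markers for motion computation.
#' @param fictive Optional point set in the same format.
#' @param roles Optional character vector of marker roles (informational).
#' @return Object of class `rigid_body_obs`.
#' @export
rigid_body_obs <- function(markers, fictive = NULL, roles = NULL) {
  markers <- as_point_matrix(markers)
  if (is.null(rownames(markers)) && nrow(markers) > 0L)
    rownames(markers) <- paste0("m", seq_len(nrow(markers)))
  if (anyDuplicated(rownames(markers)))
    stop("marker ids must be unique within a rigid body")
  if (!is.null(fictive)) {
    fictive <- as_point_matrix(fictive)
    if (is.null(rownames(fictive)))
      rownames(fictive) <- paste0("f", seq_len(nrow(fictive)))
  }
  structure(list(markers = markers, fictive = fictive, roles = roles),
            class = "rigid_body_obs")
}

#' Examination
#'
#' One patient/timepoint observation: per-rigid-body labeled 3D marker
#' positions in a named coordinate frame, with the acquisition context
#' needed for scheduling and QC checks.
#'
#' @param exam_id,patient_id Identifiers.
#' @param side `"left"` or `"right"`.
#' @param days_since_surgery Integer >= 0.
#' @param bodies Named list of [rigid_body_obs()] (e.g. `bone`,
#'   `prosthesis`).
#' @param modality `"RSA"` or `"CT_RSA"`.
#' @param kind `"baseline"`, `"followup"` or `"double"`.
#' @param weightbearing Loading state at acquisition.
#' @param frame Coordinate frame of the marker positions: `"RSA_GLOBAL"`
#'   (cage-defined) or `"DICOM_LPS"` (CT).
#' @param meta Named list of acquisition metadata (see
#'   [validate_acquisition()]).
#' @return Object of class `examination`.
#' @export
examination <- function(exam_id, patient_id, side = c("right", "left"),
                        days_since_surgery = 0L, bodies,
                        modality = c("RSA", "CT_RSA"),
                        kind = c("followup", "baseline", "double"),
                        weightbearing = c("supine", "pre", "post", "loaded"),
                        frame = c("RSA_GLOBAL", "DICOM_LPS"),
                        meta = list()) {
  side <- match.arg(side)
  modality <- match.arg(modality)
  kind <- match.arg(kind)
  weightbearing <- match.arg(weightbearing)
  frame <- match.arg(frame)
  if (days_since_surgery < 0) stop("days_since_surgery must be >= 0")
  if (!is.list(bodies) || is.null(names(bodies)) || any(names(bodies) == ""))
    stop("bodies must be a named list of rigid_body_obs")
  bodies <- lapply(bodies, function(b)
    if (inherits(b, "rigid_body_obs")) b else rigid_body_obs(b))
  structure(list(exam_id = exam_id, patient_id = patient_id, side = side,
                 days_since_surgery = as.integer(days_since_surgery),
                 bodies = bodies, modality = modality, kind = kind,
                 weightbearing = weightbearing, frame = frame, meta = meta),
            class = "examination")
}

#' Migration coordinate system specification
#'
#' The anatomic migration frame in which signed components are reported.
#' The default for right-sided RSA has the X-axis pointing medially, Y
#' superiorly, Z anteriorly, axes aligned with the global frame, and the
#' origin at the geometric center (marker centroid) of the migrating body in
#' the baseline examination. The same specification must be reused for all
#' follow-ups of a patient.
#'
#' @param origin `"geometric_center"` or `"custom"` (then give
#'   `origin_point`).
#' @param origin_point Length-3 numeric (mm, examination frame), for custom
#'   origins such as an anatomic landmark.
#' @param axes 3x3 rotation: columns are the migration X/Y/Z axis directions
#'   expressed in the examination frame. Default identity (anatomic frame
#'   aligned with the global frame by patient positioning).
#' @param labels Anatomic axis labels emitted in report metadata.
#' @return Object of class `cs_spec`.
#' @export
coordinate_system_spec <- function(origin = c("geometric_center", "custom"),
                                   origin_point = NULL,
                                   axes = diag(3),
                                   labels = c(x = "medial", y = "superior",
                                              z = "anterior")) {
  origin <- match.arg(origin)
  axes <- unname(as.matrix(axes))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9 || det(axes) < 0)
    stop("axes must form a right-handed orthonormal triad")
  if (origin == "custom" && (is.null(origin_point) || length(origin_point) != 3L))
    stop("custom origin requires origin_point (3-vector, mm)")
  structure(list(origin = origin, origin_point = origin_point, axes = axes,
                 labels = labels),
            class = "cs_spec")
}

cs_equal <- function(a, b) {
  identical(a$origin, b$origin) &&
    isTRUE(max(abs(a$axes - b$axes)) < 1e-12) &&
    (is.null(a$origin_point) == is.null(b$origin_point)) &&
    (is.null(a$origin_point) || max(abs(a$origin_point - b$origin_point)) < 1e-12)
}

#' Compute implant migration between a baseline and a follow-up examination
#'
#' The standardized two-step procedure. Step 1: the reference rigid body
#' (bone) of the follow-up is aligned to the same body in the baseline by a
#' least-squares rigid fit, which removes the difference in patient
#' position/orientation between the examinations; the fitted transform is
#' applied to the migrating body (prosthesis) of the follow-up. Step 2: the
#' residual rigid transform taking the baseline prosthesis onto the aligned
#' follow-up prosthesis is the migration.
#'
#' The migration transform is expressed in the migration frame of `cs`
#' (origin at the baseline geometric center of the migrating body by
#' default) as 3 signed translations (mm, motion of the origin along the
#' migration axes), 3 Euler rotations (degrees, body-fixed XYZ), their norms
#' TT and TR (TR flagged when outside small-angle validity, > 5 degrees),
#' per-point motions and MTPM over the evaluated point set (the migrating
#' body's fitted markers plus any fictive points).
#'
#' @param baseline,followup [examination()] objects containing both bodies.
#' @param reference_body,migrating_body Names of the bodies in
#'   `exam$bodies`.
#' @param cs A [coordinate_system_spec()].
#' @param marker_method Provenance label: `"all"` (per-pair intersection
#'   with baseline, the default behaviour) or `"consistent"` (pass the
#'   series-wide subsets from [select_markers()] via `marker_selection`).
#' @param marker_selection Optional list with elements `reference` and
#'   `migrating`: character vectors of marker ids to restrict the fits to.
#' @return Object of class `migration_result` with fields `tx`, `ty`, `tz`
#'   (mm), `rx`, `ry`, `rz` (deg), `tt`, `tr`, `mtpm`, `mtpm_point`,
#'   `point_motions` (data.frame), `quality` (per body: `me`, `cn`,
#'   `n_markers`), `transform` (migration-frame [rigid_transform()]),
#'   provenance and `warnings`.
#' @export
compute_migration <- function(baseline, followup,
                              reference_body = "bone",
                              migrating_body = "prosthesis",
                              cs = coordinate_system_spec(),
                              marker_method = c("all", "consistent"),
                              marker_selection = NULL) {
  marker_method <- match.arg(marker_method)
  stopifnot(inherits(baseline, "examination"), inherits(followup, "examination"))
  if (baseline$frame != followup$frame)
    stop("baseline and follow-up are expressed in different frames; convert first")
  warnings <- character()

  get_body <- function(exam, body) {
    if (!body %in% names(exam$bodies))
      stop(sprintf("examination %s lacks rigid body '%s'", exam$exam_id, body))
    exam$bodies[[body]]
  }
  subset_ids <- function(m, ids) {
    if (is.null(ids)) return(m)
    keep <- intersect(rownames(m), ids)
    m[keep, , drop = FALSE]
  }

  ref_base <- subset_ids(get_body(baseline, reference_body)$markers,
                         marker_selection$reference)
  ref_fu <- subset_ids(get_body(followup, reference_body)$markers,
                       marker_selection$reference)
  common_ref <- intersect(rownames(ref_base), rownames(ref_fu))
  if (length(common_ref) < 3L)
    stop(sprintf("insufficient shared markers in reference body '%s' (%d, need >= 3)",
                 reference_body, length(common_ref)))

  mig_obs <- get_body(baseline, migrating_body)
  mig_base <- subset_ids(mig_obs$markers, marker_selection$migrating)
  mig_fu <- subset_ids(get_body(followup, migrating_body)$markers,
                       marker_selection$migrating)
  common_mig <- sort(intersect(rownames(mig_base), rownames(mig_fu)))
  if (length(common_mig) < 3L)
    stop(sprintf("insufficient shared markers in migrating body '%s' (%d, need >= 3)",
                 migrating_body, length(common_mig)))

  # step 1: align follow-up to baseline through the reference body
  fit_ref <- fit_rigid(ref_base, ref_fu)
  mig_fu_aligned <- apply_transform(fit_ref$transform,
                                    mig_fu[common_mig, , drop = FALSE])

  # step 2: residual motion of the migrating body
  fit_mig <- fit_rigid(mig_fu_aligned, mig_base[common_mig, , drop = FALSE])
  R <- fit_mig$transform$rotation
  tv <- fit_mig$transform$translation
  # report CN of the baseline configuration for both bodies
  q_ref <- list(me = fit_ref$quality$me, cn = condition_number(ref_base[fit_ref$ids, , drop = FALSE]),
                n_markers = fit_ref$quality$n_markers)
  q_mig <- list(me = fit_mig$quality$me,
                cn = condition_number(mig_base[common_mig, , drop = FALSE]),
                n_markers = length(common_mig))

  origin <- if (cs$origin == "geometric_center")
    colMeans(mig_base[common_mig, , drop = FALSE]) else as.numeric(cs$origin_point)
  A <- cs$axes
  Rm <- t(A) %*% R %*% A
  tm <- as.numeric(t(A) %*% ((R - diag(3)) %*% origin + tv))
  euler <- euler_from_rotation(Rm)
  if (isTRUE(attr(euler, "gimbal_lock")))
    warnings <- c(warnings, "gimbal lock: ry at +/-90 degrees, rz set to 0")
  tt <- total_translation(tm)
  tr <- total_rotation(euler)
  if (isTRUE(attr(tr, "small_angle_warning")))
    warnings <- c(warnings, "total rotation outside small-angle validity (> 5 degrees)")

  eval_pts <- mig_base[common_mig, , drop = FALSE]
  if (!is.null(mig_obs$fictive)) eval_pts <- rbind(eval_pts, mig_obs$fictive)
  pm <- point_motions_table(eval_pts, R, tv, A)
  mt <- max(pm$norm_mm)
  mt_point <- min(pm$point_id[pm$norm_mm == mt])  # lexicographic tie-break

  structure(list(
    tx = tm[1], ty = tm[2], tz = tm[3],
    rx = unname(euler[1]), ry = unname(euler[2]), rz = unname(euler[3]),
    tt = as.numeric(tt), tr = as.numeric(tr),
    mtpm = mt, mtpm_point = mt_point, point_motions = pm,
    quality = list(reference = q_ref, migrating = q_mig),
    transform = rigid_transform(Rm, tm),
    marker_method = marker_method, cs = cs,
    side = baseline$side, side_convention = "as_measured",
    patient_id = baseline$patient_id,
    reference_body = reference_body, migrating_body = migrating_body,
    baseline_exam = baseline$exam_id, followup_exam = followup$exam_id,
    days_since_surgery = followup$days_since_surgery,
    warnings = warnings), class = "migration_result")
}

# Displacements of evaluated points under the global-frame migration (R, t),
# expressed along the migration axes A (columns = axis directions).
point_motions_table <- function(points, R, tv, A = diag(3)) {
  d <- sweep(points %*% t(R - diag(3)), 2L, tv, "+") %*% A
  data.frame(point_id = rownames(points),
             dx_mm = d[, 1], dy_mm = d[, 2], dz_mm = d[, 3],
             norm_mm = sqrt(rowSums(d^2)), row.names = NULL)
}

#' Maximum total point motion (MTPM)
#'
#' The displacement norm of the evaluated point that has moved most under a
#' migration transform, disregarding its location. Independent of the
#' orientation of the migration coordinate system; for pure translations it
#' equals the total translation for every point set. A consistent point set
#' across timepoints should be used within a patient. Ties are broken by
#' lexicographic point id.
#'
#' @param points Evaluated point set (prosthesis markers, fictive points, or
#'   model surface vertices): matrix / data.frame as in [fit_rigid()].
#' @param transform The migration [rigid_transform()] (same frame as
#'   `points`).
#' @return List with `mtpm` (mm) and `point_id` of the argmax.
#' @export
mtpm <- function(points, transform) {
  p <- as_point_matrix(points)
  if (nrow(p) == 0L) stop("empty point set")
  if (is.null(rownames(p))) rownames(p) <- paste0("p", seq_len(nrow(p)))
  pm <- point_motions_table(p, transform$rotation, transform$translation)
  m <- max(pm$norm_mm)
  list(mtpm = m, point_id = min(pm$point_id[pm$norm_mm == m]))
}

#' Motion of a single (fictive) point
#'
#' Displacement of a feature point -- e.g. a hip-stem tip or a tibial
#' baseplate corner -- under the migration transform, plus its vector
#' length.
#'
#' @param point Length-3 numeric (mm), in the transform's frame.
#' @param transform The migration [rigid_transform()].
#' @return List with `vector` (3 displacement components, mm) and `norm_mm`.
#' @export
point_motion <- function(point, transform) {
  p <- as.numeric(point)
  if (length(p) != 3L || !all(is.finite(p))) stop("point must be a finite 3-vector")
  d <- as.numeric(transform$rotation %*% p) + transform$translation - p
  list(vector = d, norm_mm = sqrt(sum(d^2)))
}

#' Marker selection across a follow-up series
#'
#' `"consistent"` restricts every examination to the markers visible in
#' *all* examinations of the series (stable individual-level trajectories,
#' but late occlusions alter early results on re-analysis); `"all"` uses,
#' per follow-up, every marker that can be matched to the baseline.
#'
#' @param baseline Baseline [examination()].
#' @param followups List of follow-up [examination()]s.
#' @param body Body name to select markers for.
#' @param method `"consistent"` or `"all"`.
#' @return Named list (by follow-up exam id) of character vectors of marker
#'   ids; `attr(, "method")` records the selection.
#' @export
select_markers <- function(baseline, followups, body = "bone",
                           method = c("consistent", "all")) {
  method <- match.arg(method)
  base_ids <- rownames(baseline$bodies[[body]]$markers)
  if (is.null(base_ids) || length(base_ids) == 0L)
    stop("baseline marker set is empty")
  fu_ids <- lapply(followups, function(e) rownames(e$bodies[[body]]$markers))
  sel <- if (method == "consistent") {
    ids <- Reduce(intersect, fu_ids, base_ids)
    if (length(ids) < 3L)
      stop(sprintf(
        "consistent-marker intersection for body '%s' has %d marker(s) (< 3); consider the all-marker method",
        body, length(ids)))
    lapply(fu_ids, function(x) sort(ids))
  } else {
    lapply(fu_ids, function(x) sort(intersect(base_ids, x)))
  }
  names(sel) <- vapply(followups, function(e) e$exam_id, character(1))
  attr(sel, "method") <- method
  sel
}

#' Interval migration by component-wise subtraction
#'
#' Migration over an interval (e.g. from the 1-year to the 2-year
#' follow-up) is obtained by subtracting the earlier from the later
#' migration, component by component -- not by recomputing with the earlier
#' follow-up as baseline. TT/TR are recomputed from the differenced
#' components and MTPM from the differenced point motions. Component
#' subtraction is exact for translations but approximate for rotations;
#' the result is flagged when either input has TR > 5 degrees.
#'
#' @param m_early,m_late [compute_migration()] results for the same patient,
#'   bodies, coordinate system and marker provenance.
#' @return A `migration_result` for the interval.
#' @export
interval_migration <- function(m_early, m_late) {
  stopifnot(inherits(m_early, "migration_result"),
            inherits(m_late, "migration_result"))
  same <- identical(m_early$patient_id, m_late$patient_id) &&
    identical(m_early$migrating_body, m_late$migrating_body) &&
    identical(m_early$reference_body, m_late$reference_body) &&
    identical(m_early$marker_method, m_late$marker_method) &&
    identical(m_early$side_convention, m_late$side_convention) &&
    cs_equal(m_early$cs, m_late$cs)
  if (!same)
    stop("mismatched provenance: interval migration needs the same patient, bodies, coordinate system, and marker method")
  out <- m_late
  for (f in c("tx", "ty", "tz", "rx", "ry", "rz"))
    out[[f]] <- m_late[[f]] - m_early[[f]]
  out$tt <- total_translation(c(out$tx, out$ty, out$tz))
  tr <- total_rotation(c(out$rx, out$ry, out$rz))
  out$tr <- as.numeric(tr)
  pm <- merge(m_late$point_motions, m_early$point_motions, by = "point_id",
              suffixes = c("_late", "_early"))
  if (nrow(pm) == 0L) stop("no common evaluated points between intervals")
  d <- cbind(pm$dx_mm_late - pm$dx_mm_early, pm$dy_mm_late - pm$dy_mm_early,
             pm$dz_mm_late - pm$dz_mm_early)
  out$point_motions <- data.frame(point_id = pm$point_id,
                                  dx_mm = d[, 1], dy_mm = d[, 2], dz_mm = d[, 3],
                                  norm_mm = sqrt(rowSums(d^2)))
  out$mtpm <- max(out$point_motions$norm_mm)
  out$mtpm_point <- min(out$point_motions$point_id[out$point_motions$norm_mm == out$mtpm])
  out$transform <- NULL  # component difference is not a composed transform
  out$warnings <- character()
  if (m_early$tr > 5 || m_late$tr > 5)
    out$warnings <- "interval subtraction approximate for large rotations (TR > 5 degrees)"
  out$baseline_exam <- m_early$followup_exam
  out$interval <- c(m_early$days_since_surgery, m_late$days_since_surgery)
  out
}

#' Convert a left-sided migration result to the right-side convention
#'
#' Group aggregation requires all results in the right-side convention:
#' for left-sided prostheses, the X translation and the rotations about the
#' Y and Z axes change sign (a mirror through the sagittal plane). Norms
#' (TT, TR, MTPM, point-motion lengths) are unchanged; point-motion X
#' components are mirrored consistently. Right-sided results pass through
#' unchanged. The conversion is an involution.
#'
#' @param result A `migration_result`.
#' @param side Override of `result$side` (`"left"`/`"right"`).
#' @return A `migration_result` with `side_convention` toggled.
#' @export
to_right_side <- function(result, side = result$side) {
  stopifnot(inherits(result, "migration_result"))
  if (is.null(side) || !side %in% c("left", "right"))
    stop("unknown side: must be 'left' or 'right'")
  out <- result
  if (side == "left") {
    out$tx <- -out$tx; out$ry <- -out$ry; out$rz <- -out$rz
    out$point_motions$dx_mm <- -out$point_motions$dx_mm
  }
  out$side_convention <-
    if (result$side_convention == "as_measured") "converted_to_right" else "as_measured"
  out
}

# Axis permutation RSA -> LPS: the left-pointing X axis is shared; RSA
# superior (+Y) is LPS +Z; RSA anterior (+Z) is LPS -Y. Proper rotation
# (det +1).
.rsa_to_lps <- rbind(c(1, 0, 0),
                     c(0, 0, -1),
                     c(0, 1, 0))

#' Convert vectors or transforms between the RSA and DICOM LPS frames
#'
#' The cage-defined RSA global frame (X left, Y superior, Z anterior) and
#' the DICOM patient frame (X left, Y posterior, Z superior) differ by a
#' fixed axis permutation; the round trip is the identity.
#'
#' @param x Length-3 numeric, n x 3 matrix, or [rigid_transform()].
#' @param from,to Frame tags: `"RSA_GLOBAL"` or `"DICOM_LPS"`.
#' @return `x` expressed in the target frame.
#' @export
convert_frame <- function(x, from, to) {
  frames <- c("RSA_GLOBAL", "DICOM_LPS")
  if (!from %in% frames || !to %in% frames)
    stop(sprintf("unknown frame tag: use %s", paste(frames, collapse = " or ")))
  if (from == to) return(x)
  M <- if (from == "RSA_GLOBAL") .rsa_to_lps else t(.rsa_to_lps)
  if (inherits(x, "rigid_transform"))
    return(rigid_transform(M %*% x$rotation %*% t(M), as.numeric(M %*% x$translation)))
  if (is.matrix(x)) return(x %*% t(M))
  as.numeric(M %*% as.numeric(x))
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("<migration_result> patient %s, %s vs %s (%s side, %s)\n",
              x$patient_id, x$followup_exam, x$baseline_exam, x$side,
              x$side_convention))
  cat(sprintf("  t (mm):  x %7.3f  y %7.3f  z %7.3f   TT %7.3f\n",
              x$tx, x$ty, x$tz, x$tt))
  cat(sprintf("  r (deg): x %7.3f  y %7.3f  z %7.3f   TR %7.3f\n",
              x$rx, x$ry, x$rz, x$tr))
  cat(sprintf("  MTPM %7.3f mm at point %s\n", x$mtpm, x$mtpm_point))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten migration results to the standard results table
#'
#' One row per computed migration with the standard column set used by the
#' QC gate, precision statistics and reporting functions.
#'
#' @param results A `migration_result` or list thereof.
#' @return data.frame with columns `patient_id`, `exam_id`, `days`, `side`,
#'   `tx_mm` ... `rz_deg`, `tt_mm`, `tr_deg`, `mtpm_mm`, `mtpm_point`,
#'   `me_ref_mm`, `me_mov_mm`, `cn_ref`, `cn_mov`, `n_markers_ref`,
#'   `n_markers_mov`, `marker_method`, `side_convention`, `warnings`.
#' @export
results_table <- function(results) {
  if (inherits(results, "migration_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) data.frame(
    patient_id = r$patient_id, exam_id = r$followup_exam,
    days = r$days_since_surgery, side = r$side,
    tx_mm = r$tx, ty_mm = r$ty, tz_mm = r$tz,
    rx_deg = r$rx, ry_deg = r$ry, rz_deg = r$rz,
    tt_mm = r$tt, tr_deg = r$tr, mtpm_mm = r$mtpm, mtpm_point = r$mtpm_point,
    me_ref_mm = r$quality$reference$me, me_mov_mm = r$quality$migrating$me,
    cn_ref = r$quality$reference$cn, cn_mov = r$quality$migrating$cn,
    n_markers_ref = r$quality$reference$n_markers,
    n_markers_mov = r$quality$migrating$n_markers,
    marker_method = r$marker_method, side_convention = r$side_convention,
    warnings = paste(r$warnings, collapse = "; "))))
}
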