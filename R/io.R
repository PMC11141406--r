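#' Read a marker coordinate table
#'
#' Reads the standard marker CSV (columns `exam_id`, `body_id`,
#' `marker_id`, `role`, `x_mm`, `y_mm`, `z_mm`, `frame`; mm, period decimal
#' separator) and assembles [examination()] objects, one per `exam_id`.
#' Markers with role `fictive` become the body's fictive point set.
#'
#' @param path CSV file path.
#' @param manifest Optional data.frame keyed by `exam_id` supplying
#'   `patient_id`, `side`, `days_since_surgery`, `kind`, `modality`.
#' @return Named list of [examination()] objects.
#' @export
read_marker_table <- function(path, manifest = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("exam_id", "body_id", "marker_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d)))
    stop(sprintf("marker table must have columns %s", paste(need, collapse = ", ")))
  if (is.null(d$role)) d$role <- "bone"
  if (is.null(d$frame)) d$frame <- "RSA_GLOBAL"
  out <- list()
  for (eid in unique(d$exam_id)) {
    sub <- d[d$exam_id == eid, ]
    bodies <- list()
    for (bid in unique(sub$body_id)) {
      b <- sub[sub$body_id == bid, ]
      fict <- b[b$role == "fictive", ]
      mk <- b[b$role != "fictive", ]
      m <- as.matrix(mk[, c("x_mm", "y_mm", "z_mm")])
      rownames(m) <- mk$marker_id
      f <- NULL
      if (nrow(fict)) {
        f <- as.matrix(fict[, c("x_mm", "y_mm", "z_mm")])
        rownames(f) <- fict$marker_id
      }
      bodies[[bid]] <- rigid_body_obs(m, fictive = f, roles = mk$role)
    }
    info <- list(patient_id = eid, side = "right", days_since_surgery = 0L,
                 kind = "followup", modality = "RSA")
    if (!is.null(manifest) && eid %in% manifest$exam_id) {
      row <- manifest[manifest$exam_id == eid, ][1, ]
      for (f2 in intersect(names(info), names(row)))
        if (!is.na(row[[f2]])) info[[f2]] <- row[[f2]]
    }
    out[[eid]] <- examination(eid, info$patient_id, info$side,
                              info$days_since_surgery, bodies,
                              modality = info$modality, kind = info$kind,
                              frame = sub$frame[1])
  }
  out
}

#' Write examinations to a marker coordinate table
#'
#' @param exams Named list of [examination()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(exams, path) {
  rows <- list()
  for (e in exams) {
    for (bid in names(e$bodies)) {
      b <- e$bodies[[bid]]
      add <- function(m, role)
        if (!is.null(m) && nrow(m))
          rows[[length(rows) + 1L]] <<- data.frame(
            exam_id = e$exam_id, body_id = bid, marker_id = rownames(m),
            role = role, x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3],
            frame = e$frame)
      add(b$markers, if (bid == "bone") "bone" else "prosthesis")
      add(b$fictive, "fictive")
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration-cage model from JSON
#'
#' Format: `{"cage_type": ..., "beam_angle_deg": ..., "fiducials":
#' [{"id", "image_id", "x", "y", "z"}, ...], "controls": [...]}`.
#'
#' @param path JSON file path.
#' @return A [calibration_cage()].
#' @export
read_cage_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_cage(j$cage_type, as.data.frame(j$fiducials),
                   as.data.frame(j$controls),
                   beam_angle_deg = j$beam_angle_deg)
}

#' @rdname read_cage_json
#' @param cage A [calibration_cage()] to serialize.
#' @export
write_cage_json <- function(cage, path) {
  jsonlite::write_json(list(cage_type = cage$cage_type,
                            beam_angle_deg = cage$beam_angle_deg,
                            fiducials = cage$fiducials,
                            controls = cage$controls),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read 2D detection tables
#'
#' CSV with columns `image_id`, `marker_id`, `u_mm`, `v_mm` (or `u`, `v`).
#'
#' @param path CSV file path.
#' @return data.frame `image_id`, `marker_id`, `u`, `v`.
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("u_mm" %in% names(d)) names(d)[names(d) == "u_mm"] <- "u"
  if ("v_mm" %in% names(d)) names(d)[names(d) == "v_mm"] <- "v"
  if (!all(c("image_id", "marker_id", "u", "v") %in% names(d)))
    stop("detections need columns image_id, marker_id, u_mm, v_mm")
  d
}

#' Read QC thresholds from a YAML override file
#'
#' Unknown keys are rejected; omitted keys keep the guideline defaults.
#'
#' @param path YAML file path (may be `NULL` for pure defaults).
#' @return A [qc_thresholds()] list.
#' @export
read_thresholds_yaml <- function(path = NULL) {
  if (is.null(path)) return(qc_thresholds())
  y <- yaml::read_yaml(path)
  known <- names(formals(qc_thresholds))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop(sprintf("unknown threshold field(s): %s", paste(bad, collapse = ", ")))
  do.call(qc_thresholds, y)
}

#' Write a results table to CSV
#'
#' @param results A [results_table()] data.frame.
#' @param path Output path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
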