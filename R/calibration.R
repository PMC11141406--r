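#' Calibration cage model
#'
#' The calibration cage defines the RSA global coordinate system. It carries
#' two classes of markers at known cage-frame positions: *fiducial* markers
#' lying in the detector-plane layer(s), used to map detector coordinates
#' into the cage frame, and *control* markers in the layer between plane and
#' focus, used to locate the two roentgen foci.
#'
#' @param cage_type `"uniplanar"` (detectors side-by-side, ~40 degree beam
#'   angle; hips, shoulders) or `"biplanar"` (perpendicular detectors, ~90
#'   degrees; knees and extremities).
#' @param fiducials,controls data.frames with columns `id`, `image_id`
#'   (`"A"`/`"B"`), `x`, `y`, `z` (mm, cage frame). At least 4 non-collinear
#'   fiducials and 2 control markers must be assigned to each image.
#' @param beam_angle_deg Nominal angle between the roentgen beams; defaults
#'   to 40 (uniplanar) or 90 (biplanar).
#' @return Object of class `calibration_cage`.
#' @seealso [calibrate_image()], [make_synthetic_cage()], [read_cage_json()]
#' @export
calibration_cage <- function(cage_type = c("uniplanar", "biplanar"),
                             fiducials, controls,
                             beam_angle_deg = NULL) {
  cage_type <- match.arg(cage_type)
  if (is.null(beam_angle_deg))
    beam_angle_deg <- if (cage_type == "uniplanar") 40 else 90
  check_cage_df <- function(d, what, min_n) {
    need <- c("id", "image_id", "x", "y", "z")
    if (!all(need %in% names(d)))
      stop(sprintf("%s must have columns %s", what, paste(need, collapse = ", ")))
    for (img in unique(d$image_id))
      if (sum(d$image_id == img) < min_n)
        stop(sprintf("image %s: need >= %d %s", img, min_n, what))
    d
  }
  structure(list(cage_type = cage_type,
                 beam_angle_deg = beam_angle_deg,
                 fiducials = check_cage_df(as.data.frame(fiducials), "fiducials", 4L),
                 controls = check_cage_df(as.data.frame(controls), "controls", 2L)),
            class = "calibration_cage")
}

# Normalized DLT homography fit: maps (u, v) to (a, b), >= 4 correspondences.
fit_homography <- function(uv, ab) {
  n <- nrow(uv)
  if (n < 4L) stop("insufficient fiducials: homography needs >= 4 points")
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sweep(p, 2L, ctr)
    s <- sqrt(2) / mean(sqrt(rowSums(d^2)))
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = d * s)
  }
  nu <- norm_pts(uv); na <- norm_pts(ab)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- c(nu$p[i, ], 1); y <- na$p[i, ]
    A[2L * i - 1L, ] <- c(-x, 0, 0, 0, y[1] * x)
    A[2L * i, ] <- c(0, 0, 0, -x, y[2] * x)
  }
  sv <- svd(A, nu = 0)
  if (sv$d[8] / sv$d[1] < 1e-10)
    stop("near-singular fiducial layout: homography underdetermined")
  H <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
  H <- solve(na$T) %*% H %*% nu$T
  H / H[3L, 3L]
}

apply_homography <- function(H, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2L)
  h <- cbind(uv, 1) %*% t(H)
  h[, 1:2, drop = FALSE] / h[, 3L]
}

#' Calibrate one roentgen projection from cage detections
#'
#' Fits the detector-to-cage-frame mapping of one image: (1) the image plane
#' is taken from the known fiducial layer (plane fitted through the fiducial
#' positions) and a projective (homography) mapping from 2D detector
#' coordinates to in-plane cage coordinates is estimated from >= 4 fiducial
#' detections; (2) the roentgen focus is recovered as the least-squares
#' intersection of the rays joining each control marker's known 3D position
#' to its mapped image point.
#'
#' @param cage A [calibration_cage()].
#' @param detections data.frame with columns `image_id`, `marker_id`, `u`,
#'   `v` (detector mm); only rows for `image_id` are used.
#' @param image_id Which image to calibrate (`"A"` or `"B"`).
#' @param dpi,bit_depth Optional acquisition metadata, stored for QC.
#' @return Object of class `projection_geometry`: plane origin `p0` and
#'   in-plane unit axes `e1`, `e2`, homography `H` (detector -> in-plane),
#'   `focus` (mm, cage frame), and `residuals` (fiducial mapping RMS, mean
#'   control ray distance, control reprojection RMS). A mean control-ray
#'   residual above 0.5 mm sets `residuals$warning`.
#' @export
calibrate_image <- function(cage, detections, image_id = detections$image_id[1],
                            dpi = NULL, bit_depth = NULL) {
  stopifnot(inherits(cage, "calibration_cage"))
  det <- detections[detections$image_id == image_id, , drop = FALSE]
  fid <- cage$fiducials[cage$fiducials$image_id == image_id, , drop = FALSE]
  ctl <- cage$controls[cage$controls$image_id == image_id, , drop = FALSE]

  fid <- merge(fid, det, by.x = "id", by.y = "marker_id")
  if (nrow(fid) < 4L)
    stop(sprintf("insufficient fiducials: %d detected for image %s, need >= 4",
                 nrow(fid), image_id))
  P <- as.matrix(fid[, c("x", "y", "z")])
  p0 <- colMeans(P)
  sv <- svd(sweep(P, 2L, p0))
  if (sv$d[2] / sv$d[1] < 1e-6)
    stop("near-singular fiducial layout: fiducials are collinear")
  if (sv$d[3] / sv$d[1] > 1e-6)
    stop("fiducials are not coplanar: cannot define the image plane")
  e1 <- sv$v[, 1L]; e2 <- sv$v[, 2L]
  ab <- cbind(sweep(P, 2L, p0) %*% e1, sweep(P, 2L, p0) %*% e2)
  uv <- as.matrix(fid[, c("u", "v")])
  H <- fit_homography(uv, ab)
  fid_rms <- sqrt(mean(rowSums((apply_homography(H, uv) - ab)^2)))

  ctl <- merge(ctl, det, by.x = "id", by.y = "marker_id")
  if (nrow(ctl) < 2L)
    stop(sprintf("insufficient control markers: %d detected for image %s, need >= 2",
                 nrow(ctl), image_id))
  q_ab <- apply_homography(H, as.matrix(ctl[, c("u", "v")]))
  Q <- sweep(q_ab[, 1L] %o% e1 + q_ab[, 2L] %o% e2, 2L, p0, "+")
  C <- as.matrix(ctl[, c("x", "y", "z")])
  # focus = point closest to all rays through (control marker, mapped plane point)
  Asum <- matrix(0, 3L, 3L); bsum <- numeric(3L)
  dirs <- C - Q
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (j in seq_len(nrow(C))) {
    M <- diag(3) - tcrossprod(dirs[j, ])
    Asum <- Asum + M
    bsum <- bsum + as.numeric(M %*% Q[j, ])
  }
  if (rcond(Asum) < 1e-12)
    stop("control rays are near-parallel: focus is unresolvable")
  focus <- as.numeric(solve(Asum, bsum))
  nrm <- sv$v[, 3L]
  if (abs(sum((focus - p0) * nrm)) < 1e-6)
    stop("recovered focus lies on the image plane")
  ray_dist <- vapply(seq_len(nrow(C)), function(j) {
    w <- focus - Q[j, ]
    sqrt(sum((w - sum(w * dirs[j, ]) * dirs[j, ])^2))
  }, numeric(1))
  # reprojection of controls: intersect focus->control ray with plane
  reproj <- vapply(seq_len(nrow(C)), function(j) {
    d <- C[j, ] - focus
    t <- sum((p0 - focus) * nrm) / sum(d * nrm)
    sqrt(sum((focus + t * d - Q[j, ])^2))
  }, numeric(1))
  res <- list(fiducial_rms_mm = fid_rms,
              control_ray_mean_mm = mean(ray_dist),
              control_reproj_rms_mm = sqrt(mean(reproj^2)),
              warning = sqrt(mean(reproj^2)) > 0.5)
  structure(list(image_id = image_id, p0 = p0, e1 = e1, e2 = e2, normal = nrm,
                 H = H, focus = focus, residuals = res,
                 dpi = dpi, bit_depth = bit_depth),
            class = "projection_geometry")
}

# Map detector (u, v) through the calibrated homography to a 3D point on the
# image plane (cage frame).
detector_to_plane <- function(geom, uv) {
  ab <- apply_homography(geom$H, uv)
  sweep(ab[, 1L] %o% geom$e1 + ab[, 2L] %o% geom$e2, 2L, geom$p0, "+")
}

#' Triangulate a marker from two calibrated projections
#'
#' Back-projects the detector point of each image into the ray joining its
#' focus and mapped image-plane point, and returns the midpoint of the
#' common perpendicular between the two rays. The length of the common
#' perpendicular (*crossing-line distance*) is returned as a per-point
#' quality measure: zero iff the rays intersect.
#'
#' @param geomA,geomB [calibrate_image()] results for images A and B.
#' @param uvA,uvB Length-2 detector coordinates (mm) of the marker in each
#'   image.
#' @return List with `position` (3-vector, mm, RSA global frame) and
#'   `crossing_mm`.
#' @export
reconstruct_point <- function(geomA, geomB, uvA, uvB) {
  o1 <- geomA$focus
  d1 <- as.numeric(detector_to_plane(geomA, uvA)) - o1
  d1 <- d1 / sqrt(sum(d1^2))
  o2 <- geomB$focus
  d2 <- as.numeric(detector_to_plane(geomB, uvB)) - o2
  d2 <- d2 / sqrt(sum(d2^2))
  cosang <- abs(sum(d1 * d2))
  if (cosang > cos(1 * pi / 180))
    stop("ill-conditioned reconstruction: rays are within 1 degree of parallel")
  # closest points on the two rays
  w0 <- o1 - o2
  a <- 1; b <- sum(d1 * d2); c <- 1
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  den <- a * c - b^2
  s <- (b * e - c * d) / den
  t <- (a * e - b * d) / den
  p1 <- o1 + s * d1
  p2 <- o2 + t * d2
  list(position = (p1 + p2) / 2, crossing_mm = sqrt(sum((p1 - p2)^2)))
}

#' Reconstruct all markers detected in both images
#'
#' @param geomA,geomB Calibrated [projection_geometry] objects.
#' @param detections data.frame `image_id`, `marker_id`, `u`, `v` for both
#'   images.
#' @return data.frame `marker_id`, `x`, `y`, `z`, `crossing_mm`; markers seen
#'   in only one image are excluded and listed (with reason `"occluded"`) in
#'   `attr(, "exclusions")`.
#' @export
reconstruct_markers <- function(geomA, geomB, detections) {
  dA <- detections[detections$image_id == geomA$image_id, , drop = FALSE]
  dB <- detections[detections$image_id == geomB$image_id, , drop = FALSE]
  common <- sort(intersect(dA$marker_id, dB$marker_id))
  only <- setdiff(union(dA$marker_id, dB$marker_id), common)
  out <- do.call(rbind, lapply(common, function(id) {
    r <- reconstruct_point(geomA, geomB,
                           unlist(dA[dA$marker_id == id, c("u", "v")][1, ]),
                           unlist(dB[dB$marker_id == id, c("u", "v")][1, ]))
    data.frame(marker_id = id, x = r$position[1], y = r$position[2],
               z = r$position[3], crossing_mm = r$crossing_mm)
  }))
  if (is.null(out))
    out <- data.frame(marker_id = character(), x = numeric(), y = numeric(),
                      z = numeric(), crossing_mm = numeric())
  attr(out, "exclusions") <-
    if (length(only)) data.frame(marker_id = sort(only), reason = "occluded")
    else data.frame(marker_id = character(), reason = character())
  out
}

#' Validate acquisition metadata against the guideline minima
#'
#' Checks recorded acquisition parameters against the recommended minima:
#' for plain stereo radiographs, at least 150 DPI spatial and 8-bit
#' grayscale resolution; for CT-based measurement, slice thickness below
#' 1.0 mm and pixel size below 0.5 mm, with metal-artifact-reduction usage
#' and effective dose treated as required reporting items. Validation never
#' aborts: it returns a (possibly empty) findings table.
#'
#' @param meta Named list of metadata. RSA: `dpi`, `bit_depth`. CT-RSA:
#'   `slice_thickness_mm`, `pixel_size_mm`, optionally `kVp`, `mAs`,
#'   `scanner`, `metal_artifact_reduction`, `effective_dose_msv`.
#' @param modality `"RSA"` or `"CT_RSA"`.
#' @param thresholds A [qc_thresholds()] list.
#' @return data.frame `field`, `value`, `limit`, `finding` (zero rows when
#'   all minima are met).
#' @export
validate_acquisition <- function(meta, modality = c("RSA", "CT_RSA"),
                                 thresholds = qc_thresholds()) {
  modality <- match.arg(modality)
  f <- list()
  add <- function(field, value, limit, finding)
    f[[length(f) + 1L]] <<- data.frame(field = field,
                                       value = if (is.null(value)) NA_real_ else as.numeric(value),
                                       limit = limit, finding = finding)
  if (modality == "RSA") {
    if (is.null(meta$dpi))
      add("dpi", NULL, thresholds$dpi_min, "DPI not recorded")
    else if (meta$dpi < thresholds$dpi_min)
      add("dpi", meta$dpi, thresholds$dpi_min,
          sprintf("DPI below minimum %g", thresholds$dpi_min))
    if (is.null(meta$bit_depth))
      add("bit_depth", NULL, thresholds$bit_depth_min, "bit depth not recorded")
    else if (meta$bit_depth < thresholds$bit_depth_min)
      add("bit_depth", meta$bit_depth, thresholds$bit_depth_min,
          sprintf("grayscale resolution below minimum %g bits", thresholds$bit_depth_min))
  } else {
    if (is.null(meta$slice_thickness_mm))
      add("slice_thickness_mm", NULL, thresholds$ct_slice_max_mm, "slice thickness not recorded")
    else if (meta$slice_thickness_mm > thresholds$ct_slice_max_mm)
      add("slice_thickness_mm", meta$slice_thickness_mm, thresholds$ct_slice_max_mm,
          sprintf("slice thickness above recommended maximum %g mm", thresholds$ct_slice_max_mm))
    if (is.null(meta$pixel_size_mm))
      add("pixel_size_mm", NULL, thresholds$ct_pixel_max_mm, "pixel size not recorded")
    else if (meta$pixel_size_mm > thresholds$ct_pixel_max_mm)
      add("pixel_size_mm", meta$pixel_size_mm, thresholds$ct_pixel_max_mm,
          sprintf("pixel size above recommended maximum %g mm", thresholds$ct_pixel_max_mm))
    if (is.null(meta$metal_artifact_reduction))
      add("metal_artifact_reduction", NULL, NA_real_,
          "metal artifact reduction usage not recorded")
    if (is.null(meta$effective_dose_msv))
      add("effective_dose_msv", NULL, NA_real_, "effective radiation dose not recorded")
  }
  if (length(f)) do.call(rbind, f)
  else data.frame(field = character(), value = numeric(), limit = numeric(),
                  finding = character())
}
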