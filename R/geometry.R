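#' Rigid transform
#'
#' A proper rigid-body transform: a 3x3 rotation matrix (orthonormal within
#' 1e-9, determinant +1 -- reflections are rejected, physical marker sets
#' cannot mirror) plus a translation vector in mm. Applied to a point `x` as
#' `R x + t`.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation length-3 numeric, mm.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' tf <- rigid_transform(rotation_from_euler(c(10, 5, 3)), c(1, 2, 3))
#' apply_transform(tf, rbind(c(0, 0, 0), c(10, 0, 0)))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("rotation must be a finite 3x3 matrix")
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite 3-vector")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal within 1e-9")
  if (det(rotation) < 0)
    stop("reflection detected: determinant must be +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  e <- euler_from_rotation(x$rotation)
  cat("<rigid_transform>\n")
  cat(sprintf("  translation (mm): %8.4f %8.4f %8.4f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  rotation (deg, body-fixed XYZ): %8.4f %8.4f %8.4f\n",
              e[1], e[2], e[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 numeric matrix (rows are points, mm); rownames carry
#'   marker ids and are preserved.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as_point_matrix(points)
  out <- points %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  rownames(out) <- rownames(points)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`. `invert_transform(a)` returns the inverse transform.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

# Coerce marker input (matrix or data.frame with marker_id/x/y/z or
# x_mm/y_mm/z_mm columns) to an n x 3 matrix with marker ids as rownames.
as_point_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% names(x)))
      c("x_mm", "y_mm", "z_mm") else c("x", "y", "z")
    m <- as.matrix(x[, cols])
    if ("marker_id" %in% names(x)) rownames(m) <- as.character(x$marker_id)
    x <- m
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must have 3 columns (x, y, z)")
  if (!all(is.finite(x))) stop("marker positions must be finite")
  colnames(x) <- c("x", "y", "z")
  x
}

# Match two marker sets by id (rownames); errors below `min_n` common markers.
match_markers <- function(reference, moving, min_n = 3L) {
  reference <- as_point_matrix(reference)
  moving <- as_point_matrix(moving)
  if (is.null(rownames(reference)) || is.null(rownames(moving))) {
    if (nrow(reference) != nrow(moving))
      stop("unlabeled marker sets must have equal size")
    ids <- as.character(seq_len(nrow(reference)))
    rownames(reference) <- rownames(moving) <- ids
  }
  ids <- sort(intersect(rownames(reference), rownames(moving)))
  if (length(ids) < min_n)
    stop(sprintf("insufficient markers: %d common marker(s), need >= %d",
                 length(ids), min_n))
  list(reference = reference[ids, , drop = FALSE],
       moving = moving[ids, , drop = FALSE], ids = ids)
}

#' Least-squares rigid-body fit between two marker sets
#'
#' Finds the rigid transform `T` minimizing the sum of squared distances
#' between `T(moving)` and `reference`, with correspondence by marker id
#' (rownames). Solved by SVD of the centered cross-covariance matrix
#' (Kabsch/Soederkvist-Wedin superposition), with the smallest singular value
#' sign-corrected so that only proper rotations (det = +1) are returned.
#'
#' The fit quality is returned alongside: `me`, the mean error of rigid-body
#' fitting (RMS of residual marker distances, mm), and `cn`, the condition
#' number of the *reference* marker configuration (see [condition_number()]).
#'
#' @param reference,moving Marker sets: n x 3 matrices with marker ids as
#'   rownames, or data.frames with `marker_id`, `x`, `y`, `z` columns. At
#'   least 3 common, non-collinear markers are required.
#' @param weights Optional per-marker weights (default: uniform).
#' @return A list of class `rigid_fit`: `transform` (a [rigid_transform()]),
#'   `quality` (list with `me`, `cn`, `n_markers`), and `ids` (markers used).
#' @examples
#' ref <- matrix(rnorm(15, sd = 20), 5, 3, dimnames = list(paste0("m", 1:5)))
#' tf <- rigid_transform(rotation_from_euler(c(2, -1, 3)), c(1, 0, -2))
#' fit <- fit_rigid(ref, apply_transform(tf, ref))
#' fit$quality$me  # 0: exact congruence
#' @export
fit_rigid <- function(reference, moving, weights = NULL) {
  m <- match_markers(reference, moving)
  n <- length(m$ids)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive, one per common marker")
  w <- weights / sum(weights)

  cn <- condition_number(m$reference)
  if (!is.finite(cn))
    stop("degenerate configuration: reference markers are collinear (condition number infinite)")

  cr <- colSums(m$reference * w)
  cm <- colSums(m$moving * w)
  Rc <- sweep(m$reference, 2L, cr)
  Mc <- sweep(m$moving, 2L, cm)
  # cross-covariance sum_i w_i r_i m_i^T
  B <- t(Rc * w) %*% Mc
  s <- svd(B)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tvec <- cr - as.numeric(R %*% cm)
  tf <- rigid_transform(R, tvec)
  me <- mean_error(m$reference, m$moving, tf)
  structure(list(transform = tf,
                 quality = list(me = me, cn = cn, n_markers = n),
                 ids = m$ids),
            class = "rigid_fit")
}

#' Mean error of rigid-body fitting (ME)
#'
#' Root mean square of the residual marker distances after applying
#' `transform` to the moving set: the standard marker-stability gauge
#' between a baseline and a follow-up examination.
#'
#' @inheritParams fit_rigid
#' @param transform A [rigid_transform()] mapping `moving` onto `reference`.
#' @return RMS residual in mm.
#' @export
mean_error <- function(reference, moving, transform) {
  m <- match_markers(reference, moving, min_n = 1L)
  res <- m$reference - apply_transform(transform, m$moving)
  sqrt(mean(rowSums(res^2)))
}

#' Condition number of a marker configuration (CN)
#'
#' Collinearity gauge of a marker cloud, computed from the singular values
#' `s1 >= s2 >= s3` of the centroid-centered 3 x n position matrix. The
#' default, dimensionless definition is `s1 / s2`: 1 for a perfectly
#' isotropic cloud, growing as the configuration stretches toward a line,
#' infinite for exactly collinear markers. High values indicate poorly
#' distributed markers. The ratio uses the *second* singular value because
#' collinearity -- not planarity -- is what makes rigid-body motion
#' determination singular: a 3-marker body is always exactly planar
#' (`s3 = 0`) yet is a perfectly valid configuration, so a ratio against
#' `s3` would gauge nothing useful there.
#'
#' Because conventions in the field attach the unit 1/mm to published CN
#' cut-offs, a `per_mm` scaling is also available which divides `s1 / s3` by
#' the configuration half-extent (largest marker distance from the
#' centroid, mm); choose the scaling that matches the convention your
#' cut-off was derived under. The default threshold machinery in
#' [qc_thresholds()] applies its limit to whichever scaling is configured.
#'
#' @param points Marker set (n >= 3): matrix or data.frame as in
#'   [fit_rigid()].
#' @param scaling `"dimensionless"` (default) or `"per_mm"`.
#' @return CN value >= 1 (dimensionless) or >= 1/half-extent (`per_mm`);
#'   `Inf` for collinear configurations.
#' @export
condition_number <- function(points, scaling = c("dimensionless", "per_mm")) {
  scaling <- match.arg(scaling)
  p <- as_point_matrix(points)
  if (nrow(p) < 3L) stop("at least 3 markers are required")
  ctr <- sweep(p, 2L, colMeans(p))
  s <- svd(ctr, nu = 0, nv = 0)$d
  if (s[1] <= 0) return(Inf)               # all markers coincident
  if (s[2] / s[1] < 1e-9) return(Inf)      # collinear
  cn <- s[1] / s[2]
  if (scaling == "per_mm") {
    half_extent <- max(sqrt(rowSums(ctr^2)))
    cn <- cn / half_extent
  }
  cn
}

#' Euler angles, body-fixed XYZ convention
#'
#' `euler_from_rotation()` decomposes a rotation matrix into the three Euler
#' rotations (degrees) about the body-fixed X, then Y, then Z axes, i.e.
#' `R = Rx(rx) Ry(ry) Rz(rz)`; `rotation_from_euler()` is the inverse. Signs
#' follow the right-hand rule: positive is counterclockwise looking down the
#' axis toward the origin.
#'
#' At gimbal lock (`ry = +/-90` within 1e-6 degrees) the X and Z rotations
#' are not separable; the solution with `rz = 0` is returned and flagged via
#' `attr(, "gimbal_lock")`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal within 1e-9).
#' @param euler Length-3 numeric `(rx, ry, rz)` in degrees.
#' @return `euler_from_rotation`: named numeric `(rx, ry, rz)` in degrees;
#'   `rotation_from_euler`: a 3x3 rotation matrix.
#' @examples
#' euler_from_rotation(rotation_from_euler(c(10, 5, 3)))
#' @export
euler_from_rotation <- function(rotation) {
  R <- unname(as.matrix(rotation))
  if (!all(dim(R) == c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-9 ||
      det(R) < 0)
    stop("input is not an orthonormal rotation matrix (det +1) within 1e-9")
  sy <- max(-1, min(1, R[1, 3]))
  ry <- asin(sy)
  gimbal <- (90 - abs(ry * 180 / pi)) < 1e-6
  if (gimbal) {
    # rx and rz only act through their sum (sy = +1) or difference (sy = -1);
    # convention: rz = 0
    rx <- atan2(R[2, 1], R[2, 2]) * sign(sy)
    if (sy < 0) rx <- atan2(-R[2, 1], R[2, 2])
    rz <- 0
  } else {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  }
  out <- c(rx = rx, ry = ry, rz = rz) * 180 / pi
  if (gimbal) out["rz"] <- 0
  attr(out, "gimbal_lock") <- gimbal
  out
}

#' @rdname euler_from_rotation
#' @export
rotation_from_euler <- function(euler) {
  e <- as.numeric(euler) * pi / 180
  if (length(e) != 3L || !all(is.finite(e))) stop("euler must be 3 finite angles")
  cx <- cos(e[1]); sx <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cz <- cos(e[3]); sz <- sin(e[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Total translation and total rotation
#'
#' Euclidean norms of the three signed translation (mm) / rotation (degrees)
#' components. Summarizing rotations by their norm is only valid for small
#' rotations; `total_rotation()` attaches `attr(, "small_angle_warning") =
#' TRUE` when any component or the norm exceeds 5 degrees.
#'
#' @param translation Length-3 numeric, mm.
#' @param euler Length-3 numeric, degrees.
#' @param limit_deg Small-angle validity limit (default 5 degrees).
#' @return Scalar norm (mm / degrees).
#' @examples
#' total_translation(c(3, 4, 0))  # 5
#' @export
total_translation <- function(translation) {
  v <- as.numeric(translation)
  if (length(v) != 3L || !all(is.finite(v))) stop("need 3 finite components")
  sqrt(sum(v^2))
}

#' @rdname total_translation
#' @export
total_rotation <- function(euler, limit_deg = 5) {
  e <- as.numeric(euler)
  if (length(e) != 3L || !all(is.finite(e))) stop("need 3 finite components")
  tr <- sqrt(sum(e^2))
  attr(tr, "small_angle_warning") <- any(abs(e) > limit_deg) || tr > limit_deg
  tr
}
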