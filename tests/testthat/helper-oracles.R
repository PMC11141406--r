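# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the rigid-fit oracle parameterizes the rotation
# by an axis-angle vector and minimizes the raw residual sum of squares with
# Levenberg-Marquardt; the triangulation oracle solves the normal equations
# of the two-ray least-squares problem directly from the true geometry.

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Brute-force least-squares superposition: minimize ||R m + t - r||^2 by
# Levenberg-Marquardt over an incremental axis-angle + translation, with the
# rotation parameterization re-centered at the current estimate between
# restarts (keeps the numerical Jacobian accurate near the optimum, so the
# oracle converges to machine precision).
brute_fit <- function(reference, moving) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 500)
  R0 <- diag(3); t0 <- rep(0, 3)
  for (round in 1:4) {
    resid_fn <- function(p) {
      R <- R0 %*% rodrigues(p[1:3])
      as.numeric(sweep(moving %*% t(R), 2, t0 + p[4:6], "+") - reference)
    }
    fit <- minpack.lm::nls.lm(par = rep(0, 6), fn = resid_fn, control = ctrl)
    R0 <- R0 %*% rodrigues(fit$par[1:3])
    t0 <- t0 + fit$par[4:6]
  }
  res <- sweep(moving %*% t(R0), 2, t0, "+") - reference
  list(rotation = R0, translation = t0,
       me = sqrt(mean(rowSums(res^2))))
}

# Angle (degrees) between two rotation matrices. acos((tr - 1)/2) cannot
# resolve angles below sqrt(2 * eps) ~ 1.2e-6 deg, so small angles are taken
# from the skew-symmetric part (sin theta) instead.
rotation_angle_deg <- function(R1, R2) {
  d <- crossprod(R1, R2)
  s <- sqrt(sum((d - t(d))^2)) / (2 * sqrt(2))   # sin(theta)
  c <- (sum(diag(d)) - 1) / 2                    # cos(theta)
  if (c > 0.5) asin(min(1, s)) * 180 / pi
  else acos(max(-1, min(1, c))) * 180 / pi
}

random_rotation <- function(max_deg = 30) {
  rotation_from_euler(runif(3, -max_deg, max_deg))
}

# Direct two-ray least-squares triangulation from the true geometry
# (independent of the homography/calibration path): point minimizing the
# summed squared distances to both focus->detection rays.
oracle_triangulate <- function(truthA, truthB, uvA, uvB) {
  ray <- function(tr, uv) {
    # invert the true plane->detector map G
    ab <- solve(tr$G, c(uv, 1))
    q <- tr$p0 + (ab[1] / ab[3]) * tr$e1 + (ab[2] / ab[3]) * tr$e2
    d <- q - tr$focus
    list(o = tr$focus, d = d / sqrt(sum(d^2)))
  }
  rA <- ray(truthA, uvA); rB <- ray(truthB, uvB)
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (r in list(rA, rB)) {
    M <- diag(3) - tcrossprod(r$d)
    A <- A + M
    b <- b + as.numeric(M %*% r$o)
  }
  as.numeric(solve(A, b))
}

# Small fully-labeled stereo pair of examinations with known prosthesis
# motion, used by the migration tests.
make_exam_pair <- function(bone, pros, motion_R = diag(3), motion_t = c(0, 0, 0),
                           repositioning = NULL, side = "right",
                           fictive = NULL, days = 365) {
  ctr <- colMeans(pros)
  pros_m <- sweep(sweep(pros, 2, ctr) %*% t(motion_R), 2, ctr + motion_t, "+")
  fict_m <- if (is.null(fictive)) NULL
            else sweep(sweep(fictive, 2, ctr) %*% t(motion_R), 2, ctr + motion_t, "+")
  b_fu <- bone; p_fu <- pros_m; f_fu <- fict_m
  if (!is.null(repositioning)) {
    b_fu <- apply_transform(repositioning, b_fu)
    p_fu <- apply_transform(repositioning, p_fu)
    if (!is.null(f_fu)) f_fu <- apply_transform(repositioning, f_fu)
  }
  list(
    baseline = examination("ex_base", "pt1", side, 5,
                           bodies = list(bone = rigid_body_obs(bone),
                                         prosthesis = rigid_body_obs(pros, fictive = fictive)),
                           kind = "baseline"),
    followup = examination("ex_fu", "pt1", side, days,
                           bodies = list(bone = rigid_body_obs(b_fu),
                                         prosthesis = rigid_body_obs(p_fu, fictive = f_fu)),
                           kind = "followup"))
}
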