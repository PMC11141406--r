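set.seed(21)
BONE <- gen_marker_config(6, 45, center = c(0, 0, 170), seed = 21, prefix = "b")
PROS <- gen_marker_config(4, 25, center = c(0, 10, 140), seed = 22, prefix = "p")
FICT <- rbind(tip = colMeans(PROS) + c(0, -55, 0),
              edge = colMeans(PROS) + c(30, 0, 5))

test_that("migration of an examination against itself is exactly zero", {
  pair <- make_exam_pair(BONE, PROS)
  r <- compute_migration(pair$baseline, pair$baseline)
  expect_equal(c(r$tx, r$ty, r$tz, r$rx, r$ry, r$rz), rep(0, 6), tolerance = 1e-12)
  expect_equal(r$tt, 0, tolerance = 1e-12)
  expect_equal(r$tr, 0, tolerance = 1e-12)
  expect_equal(r$mtpm, 0, tolerance = 1e-12)
})

test_that("pure translation is recovered and invariant to repositioning", {
  repos <- rigid_transform(rotation_from_euler(c(8, -5, 11)), c(25, -40, 15))
  pair <- make_exam_pair(BONE, PROS, motion_t = c(0.5, 0, 0),
                         repositioning = repos)
  r <- compute_migration(pair$baseline, pair$followup)
  expect_equal(r$tx, 0.5, tolerance = 1e-9)
  expect_equal(c(r$ty, r$tz, r$rx, r$ry, r$rz), rep(0, 5), tolerance = 1e-9)
  expect_equal(r$tt, 0.5, tolerance = 1e-9)
  # mtpm equals tt for every point set under pure translation
  expect_equal(r$mtpm, r$tt, tolerance = 1e-9)
  # result identical without the repositioning
  r0 <- compute_migration(make_exam_pair(BONE, PROS, motion_t = c(0.5, 0, 0))$baseline,
                          make_exam_pair(BONE, PROS, motion_t = c(0.5, 0, 0))$followup)
  expect_equal(r$tx, r0$tx, tolerance = 1e-9)
})

test_that("rotation about the migration Y-axis yields ry only, MTPM at the farthest point", {
  R2 <- rotation_from_euler(c(0, 2, 0))
  pair <- make_exam_pair(BONE, PROS, motion_R = R2,
                         repositioning = rigid_transform(rotation_from_euler(c(-3, 6, 2)),
                                                         c(12, 8, -20)))
  r <- compute_migration(pair$baseline, pair$followup)
  expect_equal(r$ry, 2, tolerance = 1e-9)
  expect_equal(c(r$tx, r$ty, r$tz, r$rx, r$rz), rep(0, 5), tolerance = 1e-8)
  # brute force over the evaluated points (prosthesis markers about centroid)
  ctr <- colMeans(PROS)
  disp <- sqrt(rowSums((sweep(PROS, 2, ctr) %*% t(R2) - sweep(PROS, 2, ctr))^2))
  expect_equal(r$mtpm, max(disp), tolerance = 1e-9)
  expect_identical(r$mtpm_point, names(which.max(disp)))
})

test_that("MTPM is frame-orientation invariant; signed components are not", {
  tf_pair <- make_exam_pair(BONE, PROS, motion_R = rotation_from_euler(c(1, 0.5, 0)),
                            motion_t = c(0.3, -0.2, 0.1))
  cs_rot <- coordinate_system_spec(axes = rotation_from_euler(c(0, 0, 30)))
  r1 <- compute_migration(tf_pair$baseline, tf_pair$followup)
  r2 <- compute_migration(tf_pair$baseline, tf_pair$followup, cs = cs_rot)
  expect_equal(r1$mtpm, r2$mtpm, tolerance = 1e-9)
  expect_equal(r1$tt, r2$tt, tolerance = 1e-9)
  expect_gt(abs(r1$tx - r2$tx), 1e-3)
  # tt/tr equal the norms of the stored components
  expect_equal(r1$tt, sqrt(r1$tx^2 + r1$ty^2 + r1$tz^2), tolerance = 1e-12)
  expect_equal(r1$tr, sqrt(r1$rx^2 + r1$ry^2 + r1$rz^2), tolerance = 1e-12)
})

test_that("standalone mtpm(): translation invariance, scaling, tie-breaks", {
  pts <- rbind(a = c(0, 0, 10), b = c(0, 0, 50))
  tr <- rigid_transform(translation = c(1, 2, 2))
  m <- mtpm(pts, tr)
  expect_equal(m$mtpm, 3)
  expect_identical(m$point_id, "a")  # tie broken lexicographically
  rot <- rigid_transform(rotation_from_euler(c(1, 0, 0)))
  m1 <- mtpm(pts, rot)
  expect_identical(m1$point_id, "b")
  d <- apply_transform(rot, pts) - pts
  expect_equal(m1$mtpm, max(sqrt(rowSums(d^2))), tolerance = 1e-12)
  # doubling the point-set scale doubles rotational MTPM
  expect_equal(mtpm(pts * 2, rot)$mtpm, 2 * m1$mtpm, tolerance = 1e-12)
  expect_error(mtpm(pts[0, ], rot), "empty")
})

test_that("point motion matches the MTPM machinery", {
  rot <- rigid_transform(rotation_from_euler(c(0, 1.5, 0)), c(0.2, 0, -0.1))
  p <- c(12, -8, 30)
  pm <- point_motion(p, rot)
  expect_equal(pm$norm_mm, sqrt(sum(pm$vector^2)))
  expect_equal(pm$vector,
               as.numeric(rot$rotation %*% p) + rot$translation - p,
               tolerance = 1e-12)
  expect_equal(point_motion(c(1, 1, 1), rigid_transform())$norm_mm, 0)
  expect_equal(point_motion(p, rigid_transform(translation = c(1, 2, 3)))$vector,
               c(1, 2, 3))
})

test_that("marker selection: consistent vs all-marker methods", {
  mk_ex <- function(id, bone_ids, day) {
    examination(id, "pt1", "right", day,
                bodies = list(bone = rigid_body_obs(BONE[bone_ids, ]),
                              prosthesis = rigid_body_obs(PROS)),
                kind = if (day == 0) "baseline" else "followup")
  }
  base <- mk_ex("e0", 1:6, 0)
  fu1 <- mk_ex("e1", 1:6, 365)
  fu2 <- mk_ex("e2", 1:5, 730)  # b6 occluded at 24 months
  cons <- select_markers(base, list(fu1, fu2), "bone", "consistent")
  expect_identical(cons$e1, sort(rownames(BONE)[1:5]))
  expect_identical(cons$e1, cons$e2)
  all_m <- select_markers(base, list(fu1, fu2), "bone", "all")
  expect_identical(all_m$e1, sort(rownames(BONE)))
  expect_identical(all_m$e2, sort(rownames(BONE)[1:5]))
  fu3 <- mk_ex("e3", 1:2, 900)
  expect_error(select_markers(base, list(fu1, fu3), "bone", "consistent"),
               "all-marker")
})

test_that("interval migration subtracts components and recomputes summaries", {
  p1 <- make_exam_pair(BONE, PROS, motion_t = c(0.4, 0.1, 0), days = 365)
  p2 <- make_exam_pair(BONE, PROS, motion_t = c(1.0, 0.3, 0), days = 730)
  m1 <- compute_migration(p1$baseline, p1$followup)
  m2 <- compute_migration(p2$baseline, p2$followup)
  iv <- interval_migration(m1, m2)
  expect_equal(iv$tx, 0.6, tolerance = 1e-9)
  expect_equal(iv$ty, 0.2, tolerance = 1e-9)
  expect_equal(iv$tt, sqrt(0.6^2 + 0.2^2), tolerance = 1e-9)
  expect_equal(iv$mtpm, sqrt(0.6^2 + 0.2^2), tolerance = 1e-9)
  # self-interval is zero
  iv0 <- interval_migration(m2, m2)
  expect_equal(c(iv0$tx, iv0$ty, iv0$tz, iv0$rx, iv0$ry, iv0$rz, iv0$mtpm),
               rep(0, 7), tolerance = 1e-12)
  # large rotations flag the approximation
  pr1 <- make_exam_pair(BONE, PROS, motion_R = rotation_from_euler(c(10, 0, 0)))
  pr2 <- make_exam_pair(BONE, PROS, motion_R = rotation_from_euler(c(0, 10, 0)))
  ivr <- interval_migration(compute_migration(pr1$baseline, pr1$followup),
                            compute_migration(pr2$baseline, pr2$followup))
  expect_match(ivr$warnings, "approximate")
  # provenance mismatch
  m_other <- m2; m_other$patient_id <- "pt2"
  expect_error(interval_migration(m1, m_other), "provenance")
})

test_that("left-to-right conversion follows the mirror rule and is an involution", {
  pair <- make_exam_pair(BONE, PROS, motion_R = rotation_from_euler(c(4, 5, 6)),
                         motion_t = c(1, 2, 3), side = "left")
  r <- compute_migration(pair$baseline, pair$followup)
  rr <- to_right_side(r)
  expect_equal(c(rr$tx, rr$ty, rr$tz), c(-r$tx, r$ty, r$tz))
  expect_equal(c(rr$rx, rr$ry, rr$rz), c(r$rx, -r$ry, -r$rz))
  expect_equal(rr$mtpm, r$mtpm)
  expect_equal(rr$tt, sqrt(rr$tx^2 + rr$ty^2 + rr$tz^2), tolerance = 1e-12)
  expect_identical(rr$side_convention, "converted_to_right")
  back <- to_right_side(rr)
  expect_equal(back$tx, r$tx)
  expect_equal(back$ry, r$ry)
  expect_identical(back$side_convention, "as_measured")
  # right-sided results pass through numerically unchanged
  pair_r <- make_exam_pair(BONE, PROS, motion_t = c(1, 0, 0), side = "right")
  r_right <- compute_migration(pair_r$baseline, pair_r$followup)
  expect_equal(to_right_side(r_right)$tx, r_right$tx)
  expect_error(to_right_side(r, side = "up"), "unknown side")
})

test_that("RSA and DICOM LPS frames interconvert by the fixed axis permutation", {
  expect_equal(convert_frame(c(0, 1, 0), "RSA_GLOBAL", "DICOM_LPS"), c(0, 0, 1))
  expect_equal(convert_frame(c(0, 0, 1), "RSA_GLOBAL", "DICOM_LPS"), c(0, -1, 0))
  expect_equal(convert_frame(c(1, 0, 0), "RSA_GLOBAL", "DICOM_LPS"), c(1, 0, 0))
  set.seed(31)
  v <- matrix(rnorm(30), 10, 3)
  expect_equal(convert_frame(convert_frame(v, "RSA_GLOBAL", "DICOM_LPS"),
                             "DICOM_LPS", "RSA_GLOBAL"), v)
  expect_equal(det(rsakit:::.rsa_to_lps), 1)
  tf <- rigid_transform(random_rotation(40), c(1, 2, 3))
  tf2 <- convert_frame(convert_frame(tf, "RSA_GLOBAL", "DICOM_LPS"),
                       "DICOM_LPS", "RSA_GLOBAL")
  expect_equal(tf2$rotation, tf$rotation, tolerance = 1e-12)
  expect_error(convert_frame(v, "RSA_GLOBAL", "SCANNER"), "unknown frame")
})

test_that("fictive points join the MTPM evaluation set", {
  rot <- rotation_from_euler(c(0, 0, 2))
  pair <- make_exam_pair(BONE, PROS, motion_R = rot, fictive = FICT)
  r <- compute_migration(pair$baseline, pair$followup)
  expect_true(all(c("tip", "edge") %in% r$point_motions$point_id))
  ctr <- colMeans(PROS)
  pts <- rbind(sweep(PROS, 2, ctr), sweep(FICT, 2, ctr))
  disp <- sqrt(rowSums((pts %*% t(rot) - pts)^2))
  expect_equal(r$mtpm, max(disp), tolerance = 1e-9)
})

test_that("insufficient shared markers error names the offending body", {
  pair <- make_exam_pair(BONE, PROS)
  crippled <- pair$followup
  crippled$bodies$bone <- rigid_body_obs(BONE[1:3, ])
  crippled$bodies$bone$markers <- crippled$bodies$bone$markers[1:2, ]
  expect_error(compute_migration(pair$baseline, crippled), "bone")
})
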