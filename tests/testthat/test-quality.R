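# A minimal results row with controllable quality fields.
res_row <- function(exam_id = "e1", me_ref = 0.1, me_mov = 0.1,
                    cn_ref = 50, cn_mov = 40, n_ref = 6L, n_mov = 4L,
                    tx = 0.1, patient_id = "P1") {
  data.frame(patient_id = patient_id, exam_id = exam_id, days = 365,
             side = "right", tx_mm = tx, ty_mm = 0, tz_mm = 0,
             rx_deg = 0, ry_deg = 0, rz_deg = 0, tt_mm = abs(tx), tr_deg = 0,
             mtpm_mm = abs(tx), mtpm_point = "m1",
             me_ref_mm = me_ref, me_mov_mm = me_mov,
             cn_ref = cn_ref, cn_mov = cn_mov,
             n_markers_ref = n_ref, n_markers_mov = n_mov,
             marker_method = "all", side_convention = "converted_to_right",
             warnings = "")
}

test_that("thresholds default to the guideline's printed values", {
  th <- qc_thresholds()
  expect_identical(th$me_max, 0.35)
  expect_identical(th$cn_max, 120)
  expect_identical(th$min_markers, 3L)
  expect_identical(th$tr_small_angle, 5)
  expect_identical(th$min_double_fraction, 0.25)
  expect_identical(th$dpi_min, 150)
  expect_identical(th$bit_depth_min, 8)
  expect_identical(th$ct_slice_max_mm, 1.0)
  expect_identical(th$ct_pixel_max_mm, 0.5)
  expect_identical(th$window_before_12m_days, 14)
  expect_identical(th$window_from_12m_fraction, 0.10)
  expect_error(qc_thresholds(me_max = -1), "positive")
})

test_that("qc_gate splits concise vs complete with machine-readable reasons", {
  rows <- rbind(res_row("ok"),
                res_row("bad_me", me_ref = 0.36),
                res_row("bad_cn", cn_mov = 130),
                res_row("at_limits", me_ref = 0.35, me_mov = 0.35,
                        cn_ref = 120, cn_mov = 120, n_ref = 3L, n_mov = 3L))
  g <- qc_gate(rows)
  expect_setequal(g$concise$exam_id, c("ok", "at_limits"))  # limits inclusive
  expect_identical(nrow(g$complete), 4L)
  expect_true(all(g$concise$exam_id %in% g$complete$exam_id))
  expect_match(g$reasons$reason[g$reasons$exam_id == "bad_me"], "ME .* above 0.35")
  expect_match(g$reasons$reason[g$reasons$exam_id == "bad_cn"], "CN .* above 120")
  # excluded set is exactly the set carrying reasons
  expect_setequal(setdiff(g$complete$exam_id, g$concise$exam_id),
                  unique(g$reasons$exam_id))
  # idempotent
  g2 <- qc_gate(g$concise)
  expect_identical(nrow(g2$concise), nrow(g$concise))
})

test_that("high CN with >= 4 stable markers can be retained with a flag", {
  row <- res_row("cn_exc", cn_mov = 130, me_ref = 0.1, me_mov = 0.1,
                 n_ref = 5L, n_mov = 5L)
  strict <- qc_gate(row)
  expect_identical(nrow(strict$concise), 0L)
  lenient <- qc_gate(row, cn_exception = TRUE)
  expect_identical(lenient$concise$exam_id, "cn_exc")
  expect_match(lenient$flags$reason, "retained")
  # the exception needs stable markers: high ME still excludes
  row2 <- res_row("cn_me", cn_mov = 130, me_mov = 0.4, n_mov = 5L)
  expect_identical(nrow(qc_gate(row2, cn_exception = TRUE)$concise), 0L)
})

test_that("double examination statistics: bias, precision, and fraction check", {
  rows <- do.call(rbind, lapply(1:4, function(i)
    res_row(sprintf("d%d", i), tx = c(0.1, -0.1, 0.3, -0.3)[i],
            patient_id = sprintf("P%d", i))))
  tab <- double_exam_stats(rows, n_study_patients = 20)
  tx <- tab[tab$outcome == "tx_mm", ]
  expect_identical(tx$n, 4L)
  expect_equal(tx$mean, 0)
  expect_equal(tx$sd, sqrt(0.2 / 3), tolerance = 1e-9)  # 0.2582
  expect_equal(attr(tab, "double_fraction"), 0.2)
  expect_match(attr(tab, "findings"), "below the recommended 25%")
  # all-zero migrations: bias 0, sd 0
  z <- do.call(rbind, lapply(1:3, function(i) res_row(sprintf("z%d", i), tx = 0)))
  tz <- double_exam_stats(z)
  expect_true(all(tz$mean == 0) && all(tz$sd == 0))
  expect_error(double_exam_stats(rows[0, ]), "no double")
  one <- double_exam_stats(rows[1, ])
  expect_true(all(is.na(one$sd)))
  expect_match(attr(one, "warnings"), "single pair")
})

test_that("double-exam precision recovers a known noise sd (chi-square band)", {
  set.seed(1)
  n <- 100; sigma <- 0.1
  comps <- matrix(rnorm(6 * n, sd = sigma), n, 6)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- res_row(sprintf("p%03d", i), patient_id = sprintf("P%03d", i))
    r[c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")] <- as.list(comps[i, ])
    r$tt_mm <- sqrt(sum(comps[i, 1:3]^2))
    r$tr_deg <- sqrt(sum(comps[i, 4:6]^2))
    r$mtpm_mm <- r$tt_mm
    r
  }))
  tab <- double_exam_stats(rows)
  # pooled across the 6 components: 6 (n - 1) degrees of freedom
  comps6 <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  s_pool <- sqrt(mean(tab$sd[tab$outcome %in% comps6]^2))
  df <- 6 * (n - 1)
  band <- sigma * sqrt(qchisq(c(0.025, 0.975), df) / df)
  expect_gt(s_pool, band[1])
  expect_lt(s_pool, band[2])
  # each component alone stays within its family-wise adjusted band
  band1 <- sigma * sqrt(qchisq(c(0.025 / 6, 1 - 0.025 / 6), n - 1) / (n - 1))
  for (oc in comps6) {
    s <- tab$sd[tab$outcome == oc]
    expect_gt(s, band1[1])
    expect_lt(s, band1[2])
  }
})

test_that("accuracy_vs_gold reports trueness and precision of differences", {
  truth <- data.frame(pose_id = 1:4, tx_mm = c(0, 0.5, 1, 1.5),
                      mtpm_mm = c(0, 0.5, 1, 1.5))
  perfect <- truth
  acc <- accuracy_vs_gold(perfect, truth)
  expect_true(all(acc$bias == 0) && all(acc$sd == 0))
  offset <- truth; offset$tx_mm <- truth$tx_mm + 0.2
  acc2 <- accuracy_vs_gold(offset, truth)
  expect_equal(acc2$bias[acc2$outcome == "tx_mm"], 0.2)
  expect_equal(acc2$sd[acc2$outcome == "tx_mm"], 0)
  expect_error(accuracy_vs_gold(truth[1:3, ], truth), "unpaired")
  # matches a direct recomputation on noisy data
  set.seed(2)
  noisy <- truth; noisy$tx_mm <- truth$tx_mm + rnorm(4, 0.05, 0.1)
  acc3 <- accuracy_vs_gold(noisy, truth)
  d <- noisy$tx_mm - truth$tx_mm
  expect_equal(acc3$bias[acc3$outcome == "tx_mm"], mean(d))
  expect_equal(acc3$sd[acc3$outcome == "tx_mm"], sd(d))
})

test_that("Bland-Altman limits of agreement", {
  a <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  ba1 <- bland_altman(a + 0.1, a)
  expect_equal(ba1$bias, 0.1)
  expect_equal(ba1$sd, 0)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
  # known difference distribution is recovered and LoA cover ~95%
  set.seed(3)
  base <- rnorm(500, 1, 0.5)
  d <- rnorm(500, 0.05, 0.1)
  ba <- bland_altman(base + d, base)
  expect_lt(abs(ba$bias - 0.05), 0.02)
  expect_lt(abs(ba$sd - 0.1), 0.02)
  inside <- mean(ba$data$diff >= ba$loa_lower & ba$data$diff <= ba$loa_upper)
  expect_gt(inside, 0.92)
  expect_lt(inside, 0.98)
})

test_that("follow-up scheduling windows and late-baseline flag", {
  chk <- followup_window_check(c(49, 850), baseline_day = 20)
  expect_identical(chk$assignments$timepoint, c(42, 730))
  expect_true(chk$assignments$in_window[1])   # 42 +/- 14 covers day 49
  expect_false(chk$assignments$in_window[2])  # 730 +/- 73 misses day 850
  expect_true(any(grepl("outside window", chk$findings)))
  expect_true(any(grepl("late baseline", chk$findings)))
  none <- followup_window_check(c(42, 365), baseline_day = 7)
  expect_length(none$findings, 0)
})

test_that("sample size closed form and dropout inflation", {
  expect_identical(sample_size(delta = 1, sd = 1)$n_unadjusted, 16)
  ss <- sample_size(delta = 0.2, sd = 0.3)
  expect_identical(ss$n_unadjusted, 36)
  expect_identical(sample_size(delta = 0.2, sd = 0.3, dropout = 0.2)$n_per_group, 45)
  expect_error(sample_size(delta = 0, sd = 0.3), "non-zero")
  # monotonicity: non-increasing in delta, non-decreasing in sd and power
  n_delta <- sapply(c(0.1, 0.2, 0.4), function(d) sample_size(d, 0.3)$n_unadjusted)
  expect_true(all(diff(n_delta) <= 0))
  n_sd <- sapply(c(0.2, 0.3, 0.5), function(s) sample_size(0.2, s)$n_unadjusted)
  expect_true(all(diff(n_sd) >= 0))
  n_pow <- sapply(c(0.8, 0.9, 0.95), function(p)
    sample_size(0.2, 0.3, power = p)$n_unadjusted)
  expect_true(all(diff(n_pow) >= 0))
})

test_that("posterior revision risk follows the odds-form Bayes update", {
  expect_equal(posterior_revision_risk(0.05, 0.8, 0.9, TRUE), 0.2962963,
               tolerance = 1e-6)
  # uninformative test (LR = 1) leaves the prior unchanged
  expect_equal(posterior_revision_risk(0.3, 0.7, 0.3, TRUE), 0.3, tolerance = 1e-12)
  expect_identical(posterior_revision_risk(0, 0.8, 0.9, TRUE), 0)
  expect_warning(p1 <- posterior_revision_risk(0.05, 0.8, 1, TRUE), "posterior is 1")
  expect_identical(p1, 1)
  # monotone in the prior
  priors <- seq(0.05, 0.9, by = 0.05)
  post <- sapply(priors, posterior_revision_risk, sensitivity = 0.8,
                 specificity = 0.9, classified_positive = TRUE)
  expect_true(all(diff(post) > 0))
  expect_error(posterior_revision_risk(1.2, 0.8, 0.9, TRUE), "prior")
})

test_that("second-year migration classification against a chosen threshold", {
  expect_identical(classify_migration(0.05, 0.2), "stable")
  expect_identical(classify_migration(0.25, 0.2), "continuous")
  expect_identical(classify_migration(NA, 0.2), "indeterminate")
  expect_error(classify_migration(0.25), "threshold")
})
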