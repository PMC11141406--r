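STUDY <- gen_study(study_scenario(groups = list(
  a = list(n_patients = 6, model = migration_model("plateau"), noise_sd = 0.04),
  b = list(n_patients = 6, model = migration_model("continuous",
                                                   translation = c(0.2, 0.4, 0.1),
                                                   rotation = c(0.2, 0.2, 0.1)),
           noise_sd = 0.04)),
  double_fraction = 0.34, occlusion_prob = 0, seed = 14))
AN <- analyze_study(STUDY)

test_that("outcome table summarizes cells and group differences", {
  res <- AN$results[AN$results$kind == "followup", ]
  tab <- outcome_table(res, outcomes = c("ty_mm", "mtpm_mm"))
  cell <- tab[tab$outcome == "ty_mm" & tab$timepoint == 730 & tab$group == "a", ]
  x <- res$ty_mm[res$group == "a" & res$timepoint == 730]
  expect_identical(cell$n, length(x))
  expect_equal(cell$center, mean(x))
  half <- qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
  expect_equal(cell$hi - cell$center, half, tolerance = 1e-9)
  # group mean lies inside its own CI
  expect_true(cell$lo < cell$center && cell$center < cell$hi)
  # two-group design gets difference rows
  expect_true("difference" %in% tab$group)
  diff_row <- tab[tab$group == "difference" & tab$outcome == "ty_mm" &
                    tab$timepoint == 730, ]
  xb <- res$ty_mm[res$group == "b" & res$timepoint == 730]
  expect_equal(diff_row$center, mean(x) - mean(xb), tolerance = 1e-9)
  # median/IQR style
  tmed <- outcome_table(res, outcomes = "ty_mm", style = "median_iqr")
  mcell <- tmed[tmed$outcome == "ty_mm" & tmed$timepoint == 730 & tmed$group == "a", ]
  expect_equal(mcell$center, median(x))
  expect_equal(mcell$lo, quantile(x, 0.25, names = FALSE))
  # mean_sd style carries the sd in lo/hi
  tsd <- outcome_table(res, outcomes = "ty_mm", style = "mean_sd")
  scell <- tsd[tsd$outcome == "ty_mm" & tsd$timepoint == 730 & tsd$group == "a", ]
  expect_equal(scell$lo, sd(x))
})

test_that("empty and single-observation cells are reported, not dropped", {
  res <- AN$results[AN$results$kind == "followup" &
                      !(AN$results$group == "a" & AN$results$timepoint == 730), ]
  res1 <- rbind(res,
                AN$results[AN$results$kind == "followup" &
                             AN$results$group == "a" &
                             AN$results$timepoint == 730, ][1, ])
  tab <- outcome_table(res1, outcomes = "tx_mm")
  single <- tab[tab$group == "a" & tab$timepoint == 730, ]
  expect_identical(single$n, 1L)
  expect_true(is.na(single$lo))
  expect_match(attr(tab, "warnings"), "single result", all = FALSE)
  res0 <- res[!(res$group == "a" & res$timepoint == 730), ]
  tab0 <- outcome_table(res0, outcomes = "tx_mm")
  empty <- tab0[tab0$group == "a" & tab0$timepoint == 730, ]
  expect_identical(empty$n, 0L)
})

test_that("checklist report: derivable items computed, rest flagged missing", {
  rep <- checklist_report(STUDY, AN$results,
                          config = list(technique.software = "rsakit 0.1.0"))
  expect_s3_class(rep, "checklist_report")
  # stable item registry
  expect_identical(rep$id, checklist_items()$id)
  expect_identical(rep$status[rep$id == "technique.software"], "provided")
  expect_identical(rep$status[rep$id == "ct.scanner"], "missing")
  # timing statistics equal direct recomputation
  base_days <- sapply(STUDY$exams[sapply(STUDY$exams, function(e)
    e$kind == "baseline")], function(e) e$days_since_surgery)
  want <- sprintf("mean %.1f, SD %.1f days (n = %d)", mean(base_days),
                  sd(base_days), length(base_days))
  expect_identical(rep$value[rep$id == "followup.baseline_timing"], want)
  expect_identical(rep$status[rep$id == "results.quality_summary"], "provided")
  md <- format(rep)
  expect_match(md, "## Outcome")
  expect_match(md, "rsakit 0.1.0", fixed = TRUE)
})

test_that("flow report conserves counts and attributes reasons", {
  gate <- qc_gate(AN$results)
  fr <- flow_report(STUDY, gate$concise[gate$concise$kind == "followup", ],
                    exclusions = AN$exclusions, qc = gate)
  expect_true(all(fr$expected == fr$analyzed + fr$missing))
  reason_cols <- c("occlusion", "quality_gate", "out_of_window", "dropout", "other")
  expect_true(all(rowSums(fr[, reason_cols]) == fr$missing))
  # no exclusions in this clean study
  clean <- flow_report(STUDY, AN$results[AN$results$kind == "followup", ],
                       exclusions = AN$exclusions)
  expect_true(all(clean$missing == 0))
  # inject occlusion failures and watch them appear with the right reason
  occl_study <- gen_study(study_scenario(groups = list(
    a = list(n_patients = 5, model = migration_model("plateau"), noise_sd = 0.03)),
    double_fraction = 0, occlusion_prob = 0.45, seed = 16))
  an2 <- analyze_study(occl_study)
  fr2 <- flow_report(occl_study, an2$results[an2$results$kind == "followup", ],
                     exclusions = an2$exclusions)
  expect_true(all(fr2$expected == fr2$analyzed + fr2$missing))
  expect_equal(sum(fr2$occlusion), sum(an2$exclusions$kind == "followup"))
})

test_that("marker tables and cage models round-trip through their file formats", {
  tmp <- tempfile(fileext = ".csv")
  exams <- STUDY$exams[1:3]
  write_marker_table(exams, tmp)
  manifest <- data.frame(exam_id = names(exams),
                         patient_id = sapply(exams, function(e) e$patient_id),
                         side = sapply(exams, function(e) e$side),
                         days_since_surgery = sapply(exams, function(e)
                           e$days_since_surgery),
                         kind = sapply(exams, function(e) e$kind))
  back <- read_marker_table(tmp, manifest)
  expect_setequal(names(back), names(exams))
  e0 <- exams[[1]]; e1 <- back[[e0$exam_id]]
  expect_equal(e1$bodies$bone$markers, e0$bodies$bone$markers, tolerance = 1e-9)
  expect_equal(e1$bodies$prosthesis$fictive, e0$bodies$prosthesis$fictive,
               tolerance = 1e-9)
  expect_identical(e1$side, e0$side)
  cage <- make_synthetic_cage("biplanar")$cage
  tmpj <- tempfile(fileext = ".json")
  write_cage_json(cage, tmpj)
  cage2 <- read_cage_json(tmpj)
  expect_identical(cage2$cage_type, "biplanar")
  expect_equal(cage2$fiducials$x, cage$fiducials$x)
  # thresholds YAML override
  tmpy <- tempfile(fileext = ".yaml")
  writeLines("me_max: 0.2", tmpy)
  th <- read_thresholds_yaml(tmpy)
  expect_identical(th$me_max, 0.2)
  expect_identical(th$cn_max, 120)
  writeLines("bogus_key: 1", tmpy)
  expect_error(read_thresholds_yaml(tmpy), "unknown threshold")
})

test_that("thresholds override changes concise-set membership deterministically", {
  gate_default <- qc_gate(AN$results)
  strict <- qc_thresholds(me_max = 0.01)
  gate_strict <- qc_gate(AN$results, strict)
  expect_lt(nrow(gate_strict$concise), nrow(gate_default$concise))
  expect_true(all(gate_strict$concise$me_ref_mm <= 0.01))
})
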