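#' Guideline quality thresholds
#'
#' The operative defaults of every numeric recommendation used by the QC
#' machinery. Threshold comparisons are inclusive: a value exactly at a
#' limit passes (the limits are stated as upper/lower bounds).
#'
#' @param me_max Upper limit for the mean error of rigid-body fitting (mm).
#' @param cn_max Upper limit for the condition number (hip/knee/shoulder
#'   studies; smaller joints may need higher values -- then validate
#'   precision with double examinations).
#' @param min_markers Minimum markers per rigid body.
#' @param tr_small_angle Small-angle validity limit for TR (degrees).
#' @param min_double_fraction Minimum fraction of study patients with double
#'   examinations.
#' @param dpi_min,bit_depth_min Detector resolution minima for plain RSA.
#' @param ct_slice_max_mm,ct_pixel_max_mm CT acquisition maxima for CT-RSA.
#' @param window_before_12m_days Follow-up scheduling window before 12
#'   months (+/- days).
#' @param window_from_12m_fraction Scheduling window at/after 12 months
#'   (+/- fraction of the nominal day).
#' @param baseline_max_days Latest acceptable baseline day (comparability
#'   with literature values).
#' @param cn_scaling Condition-number scaling the `cn_max` limit applies to
#'   (see [condition_number()]).
#' @return Named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(me_max = 0.35, cn_max = 120, min_markers = 3L,
                          tr_small_angle = 5, min_double_fraction = 0.25,
                          dpi_min = 150, bit_depth_min = 8,
                          ct_slice_max_mm = 1.0, ct_pixel_max_mm = 0.5,
                          window_before_12m_days = 14,
                          window_from_12m_fraction = 0.10,
                          baseline_max_days = 14,
                          cn_scaling = c("dimensionless", "per_mm")) {
  th <- list(me_max = me_max, cn_max = cn_max, min_markers = as.integer(min_markers),
             tr_small_angle = tr_small_angle,
             min_double_fraction = min_double_fraction,
             dpi_min = dpi_min, bit_depth_min = bit_depth_min,
             ct_slice_max_mm = ct_slice_max_mm, ct_pixel_max_mm = ct_pixel_max_mm,
             window_before_12m_days = window_before_12m_days,
             window_from_12m_fraction = window_from_12m_fraction,
             baseline_max_days = baseline_max_days,
             cn_scaling = match.arg(cn_scaling))
  num <- vapply(th[names(th) != "cn_scaling"], as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all thresholds must be positive and finite")
  if (th$min_double_fraction >= 1) stop("min_double_fraction must be < 1")
  structure(th, class = "qc_thresholds")
}

#' Quality gate: concise vs complete dataset
#'
#' Splits a results table into the *concise* dataset -- results meeting the
#' ME/CN/marker-count criteria on both rigid bodies -- and the *complete*
#' dataset (everything). Both should be analyzed and differences discussed.
#' Exclusions carry machine-readable reasons that feed the study flow
#' report. Optionally, results whose CN exceeds the limit but that retain at
#' least 4 stable markers (ME within its limit) are kept with a flag.
#'
#' The gate is idempotent and the concise set is always a subset of the
#' complete set.
#'
#' @param results Results table from [results_table()] (or a list of
#'   `migration_result`s).
#' @param thresholds A [qc_thresholds()] list.
#' @param cn_exception Accept high CN with >= 4 stable markers?
#' @return List: `concise` and `complete` data.frames, `reasons`
#'   (data.frame `exam_id`, `patient_id`, `field`, `value`, `limit`,
#'   `reason`), and `flags` (retained-with-flag rows).
#' @export
qc_gate <- function(results, thresholds = qc_thresholds(), cn_exception = FALSE) {
  if (!is.data.frame(results)) results <- results_table(results)
  reasons <- list(); flags <- list()
  keep <- rep(TRUE, nrow(results))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    fail <- list()
    add <- function(field, value, limit, reason)
      fail[[length(fail) + 1L]] <<- data.frame(
        exam_id = r$exam_id, patient_id = r$patient_id,
        field = field, value = value, limit = limit, reason = reason)
    if (r$me_ref_mm > thresholds$me_max)
      add("me_ref_mm", r$me_ref_mm, thresholds$me_max,
          sprintf("ME (reference body) above %g mm", thresholds$me_max))
    if (r$me_mov_mm > thresholds$me_max)
      add("me_mov_mm", r$me_mov_mm, thresholds$me_max,
          sprintf("ME (migrating body) above %g mm", thresholds$me_max))
    cn_fail <- list()
    if (!is.finite(r$cn_ref) || r$cn_ref > thresholds$cn_max)
      cn_fail$ref <- data.frame(exam_id = r$exam_id, patient_id = r$patient_id,
                                field = "cn_ref", value = r$cn_ref,
                                limit = thresholds$cn_max,
                                reason = sprintf("CN (reference body) above %g", thresholds$cn_max))
    if (!is.finite(r$cn_mov) || r$cn_mov > thresholds$cn_max)
      cn_fail$mov <- data.frame(exam_id = r$exam_id, patient_id = r$patient_id,
                                field = "cn_mov", value = r$cn_mov,
                                limit = thresholds$cn_max,
                                reason = sprintf("CN (migrating body) above %g", thresholds$cn_max))
    if (r$n_markers_ref < thresholds$min_markers)
      add("n_markers_ref", r$n_markers_ref, thresholds$min_markers,
          sprintf("fewer than %d markers (reference body)", thresholds$min_markers))
    if (r$n_markers_mov < thresholds$min_markers)
      add("n_markers_mov", r$n_markers_mov, thresholds$min_markers,
          sprintf("fewer than %d markers (migrating body)", thresholds$min_markers))

    cn_ok_by_exception <- cn_exception && length(cn_fail) > 0L &&
      length(fail) == 0L &&
      all(is.finite(c(r$cn_ref, r$cn_mov))) &&
      r$n_markers_ref >= 4L && r$n_markers_mov >= 4L &&
      r$me_ref_mm <= thresholds$me_max && r$me_mov_mm <= thresholds$me_max
    if (cn_ok_by_exception) {
      for (cf in cn_fail) {
        cf$reason <- paste0(cf$reason, " (retained: >= 4 stable markers)")
        flags[[length(flags) + 1L]] <- cf
      }
    } else {
      fail <- c(fail, unname(cn_fail))
    }
    if (length(fail)) {
      keep[i] <- FALSE
      reasons <- c(reasons, fail)
    }
  }
  empty <- data.frame(exam_id = character(), patient_id = character(),
                      field = character(), value = numeric(),
                      limit = numeric(), reason = character())
  list(concise = results[keep, , drop = FALSE],
       complete = results,
       reasons = if (length(reasons)) do.call(rbind, reasons) else empty,
       flags = if (length(flags)) do.call(rbind, flags) else empty)
}

.outcome_cols <- c(tx_mm = "tx_mm", ty_mm = "ty_mm", tz_mm = "tz_mm",
                   rx_deg = "rx_deg", ry_deg = "ry_deg", rz_deg = "rz_deg",
                   tt_mm = "tt_mm", tr_deg = "tr_deg", mtpm_mm = "mtpm_mm")

#' Double-examination precision statistics
#'
#' Double examinations are two same-day examinations with patient and
#' equipment repositioned; true motion is zero, so the measured "migration"
#' between them quantifies the measurement error. Per outcome (3
#' translations, 3 rotations, TT, TR, MTPM) and per group this returns the
#' number of pairs, the mean (bias) and the sample standard deviation
#' (precision, n - 1 denominator).
#'
#' @param pairs Results table of zero-motion migrations (one row per double
#'   pair), e.g. from [results_table()].
#' @param group Optional name of a grouping column in `pairs`.
#' @param n_study_patients Optional total number of study patients; when
#'   given, the double-examination fraction is checked against
#'   `thresholds$min_double_fraction` and reported in
#'   `attr(, "double_fraction")` / `attr(, "findings")`.
#' @param thresholds A [qc_thresholds()] list.
#' @return data.frame of class `double_exam_table`: `group`, `outcome`,
#'   `n`, `mean`, `sd`, `unit`.
#' @export
double_exam_stats <- function(pairs, group = NULL, n_study_patients = NULL,
                              thresholds = qc_thresholds()) {
  if (!is.data.frame(pairs)) pairs <- results_table(pairs)
  if (nrow(pairs) == 0L) stop("no double-examination pairs supplied")
  grp <- if (is.null(group)) rep("all", nrow(pairs)) else as.character(pairs[[group]])
  out <- list(); warn <- character()
  for (g in unique(grp)) {
    sub <- pairs[grp == g, , drop = FALSE]
    for (oc in names(.outcome_cols)) {
      x <- sub[[oc]]
      n <- sum(is.finite(x))
      if (n == 1L) warn <- c(warn, sprintf("group %s: single pair, SD unavailable", g))
      out[[length(out) + 1L]] <- data.frame(
        group = g, outcome = oc, n = n,
        mean = if (n) mean(x, na.rm = TRUE) else NA_real_,
        sd = if (n >= 2L) stats::sd(x, na.rm = TRUE) else NA_real_,
        unit = if (grepl("_deg$", oc)) "deg" else "mm")
    }
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("double_exam_table", class(tab))
  findings <- character()
  if (!is.null(n_study_patients)) {
    frac <- length(unique(pairs$patient_id)) / n_study_patients
    attr(tab, "double_fraction") <- frac
    if (frac < thresholds$min_double_fraction)
      findings <- c(findings, sprintf(
        "double examinations cover %.0f%% of study patients, below the recommended %.0f%%",
        100 * frac, 100 * thresholds$min_double_fraction))
  }
  attr(tab, "findings") <- findings
  attr(tab, "warnings") <- unique(warn)
  tab
}

#' Accuracy against a gold standard (phantom experiment)
#'
#' Summarizes measured-minus-truth differences per outcome: *trueness* (the
#' mean difference, i.e. bias / systematic error) and *precision* (the
#' standard deviation of differences, i.e. random error). Signed components
#' (tx..rz) are differenced as signed values; MTPM/TT/TR are unsigned
#' metrics whose (signed) difference of unsigned values is reported. The
#' gold standard should come from an apparatus at least 10x more accurate
#' than the method under test (exact by construction for the synthetic
#' phantom); the declared gold-standard precision, if provided, is checked.
#'
#' @param measured,truth data.frames with a shared `pose_id` key and outcome
#'   columns (`tx_mm` ... `mtpm_mm`; missing columns are skipped).
#' @param by Key column (default `"pose_id"`).
#' @param gold_precision_mm Optional declared accuracy of the gold-standard
#'   apparatus; a finding is attached when it is not at least 10x smaller
#'   than the observed precision.
#' @return data.frame of class `accuracy_table`: `outcome`, `n`, `bias`,
#'   `sd`, `unit`.
#' @export
accuracy_vs_gold <- function(measured, truth, by = "pose_id",
                             gold_precision_mm = NULL) {
  m <- merge(measured, truth, by = by, suffixes = c("_meas", "_true"))
  if (nrow(m) != nrow(measured) || nrow(m) != nrow(truth))
    stop("unpaired rows: measured and truth must match one-to-one on the key")
  out <- list()
  for (oc in names(.outcome_cols)) {
    cm <- paste0(oc, "_meas"); ct <- paste0(oc, "_true")
    if (!cm %in% names(m) || !ct %in% names(m)) next
    d <- m[[cm]] - m[[ct]]
    out[[length(out) + 1L]] <- data.frame(
      outcome = oc, n = length(d), bias = mean(d),
      sd = if (length(d) >= 2L) stats::sd(d) else NA_real_,
      unit = if (grepl("_deg$", oc)) "deg" else "mm")
  }
  if (!length(out)) stop("no shared outcome columns between measured and truth")
  tab <- do.call(rbind, out)
  class(tab) <- c("accuracy_table", class(tab))
  if (!is.null(gold_precision_mm)) {
    prec <- tab$sd[tab$outcome == "tt_mm"]
    if (length(prec) && is.finite(prec) && gold_precision_mm > prec / 10)
      attr(tab, "findings") <- sprintf(
        "gold standard precision %g mm is not 10x better than the observed precision %g mm",
        gold_precision_mm, prec)
  }
  tab
}

#' Bland-Altman comparison of two measurement methods
#'
#' For comparing two migration-measurement methods without a gold standard:
#' per-subject differences against means, the mean difference (bias), the
#' SD of differences, and the 95% limits of agreement `bias +/- 1.96 sd`.
#'
#' @param method_a,method_b Paired numeric vectors (same subjects, same
#'   order).
#' @return List of class `bland_altman`: `n`, `bias`, `sd`, `loa_lower`,
#'   `loa_upper`, and `data` (data.frame `mean`, `diff`) for plotting.
#' @export
bland_altman <- function(method_a, method_b) {
  a <- as.numeric(method_a); b <- as.numeric(method_b)
  if (length(a) != length(b)) stop("methods must be paired (equal length)")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("Bland-Altman needs at least 3 pairs")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  structure(list(n = length(d), bias = bias, sd = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 data = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' Check follow-up scheduling against the protocol windows
#'
#' Each examination is assigned to the nearest protocol timepoint and
#' checked against the scheduling window: +/- 2 weeks for timepoints before
#' 12 months and +/- 10% of the nominal day for 12 months and later. A
#' baseline examination later than 2 weeks postoperatively is flagged as a
#' comparability limitation (migration values are then not comparable with
#' literature using early baselines).
#'
#' @param days Integer vector: days since surgery of the follow-up
#'   examinations.
#' @param timepoints Protocol timepoints in days (default: 6 weeks, 3, 6,
#'   12, 24 months).
#' @param baseline_day Optional baseline examination day.
#' @param thresholds A [qc_thresholds()] list.
#' @return List: `assignments` (data.frame `day`, `timepoint`, `window_lo`,
#'   `window_hi`, `in_window`) and `findings` (character).
#' @export
followup_window_check <- function(days, timepoints = c(42, 91, 182, 365, 730),
                                  baseline_day = NULL,
                                  thresholds = qc_thresholds()) {
  days <- as.numeric(days)
  tp <- vapply(days, function(d) timepoints[which.min(abs(timepoints - d))], numeric(1))
  half <- ifelse(tp < 365, thresholds$window_before_12m_days,
                 thresholds$window_from_12m_fraction * tp)
  asg <- data.frame(day = days, timepoint = tp,
                    window_lo = tp - half, window_hi = tp + half,
                    in_window = days >= tp - half & days <= tp + half)
  findings <- sprintf("examination at day %g outside window [%g, %g] of timepoint %g",
                      asg$day[!asg$in_window], asg$window_lo[!asg$in_window],
                      asg$window_hi[!asg$in_window], asg$timepoint[!asg$in_window])
  if (!is.null(baseline_day) && baseline_day > thresholds$baseline_max_days)
    findings <- c(findings, sprintf(
      "late baseline (day %g > %g) - comparability limitation",
      baseline_day, thresholds$baseline_max_days))
  list(assignments = asg, findings = findings)
}

#' Sample size for a two-group migration trial
#'
#' Two-sample normal-approximation formula
#' `n = 2 (z[1-alpha/2] + z[power])^2 sd^2 / delta^2` per group, rounded up,
#' then inflated by `1 / (1 - dropout)` to compensate for expected dropouts
#' (including RSA technical failures such as occluded or unstable markers).
#'
#' @param delta Minimal clinically relevant group difference (mm or
#'   degrees).
#' @param sd Expected standard deviation of the outcome (same unit).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Desired power (default 0.80).
#' @param dropout Expected dropout fraction in `[0, 1)`.
#' @return List: `n_per_group` (after dropout inflation), `n_unadjusted`.
#' @examples
#' sample_size(delta = 0.2, sd = 0.3)$n_unadjusted          # 36
#' sample_size(delta = 0.2, sd = 0.3, dropout = 0.2)$n_per_group  # 45
#' @export
sample_size <- function(delta, sd, alpha = 0.05, power = 0.80, dropout = 0) {
  if (delta == 0) stop("delta must be non-zero")
  if (delta < 0 || sd <= 0) stop("delta and sd must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n0 <- ceiling(2 * z^2 * sd^2 / delta^2)
  list(n_per_group = ceiling(n0 / (1 - dropout)), n_unadjusted = n0)
}

#' Posterior revision risk after a migration classification
#'
#' Bayes update of the revision risk from a screening or diagnostic
#' migration test: the prior (pre-test) probability -- the overall revision
#' risk for the implant design -- is updated through the likelihood ratio
#' of the classification, `LR+ = sens / (1 - spec)` for a positive call
#' (continuous migration) and `LR- = (1 - sens) / spec` for a negative one.
#' The same classification can therefore imply very different post-test
#' risks for implants with different background revision rates.
#'
#' @param prior Pre-test probability of revision/loosening, in `[0, 1]`.
#' @param sensitivity,specificity Test characteristics, in `(0, 1]`.
#' @param classified_positive Was the patient classified as continuously
#'   migrating?
#' @return Posterior probability.
#' @examples
#' posterior_revision_risk(0.05, 0.8, 0.9, TRUE)  # ~0.296
#' @export
posterior_revision_risk <- function(prior, sensitivity, specificity,
                                    classified_positive = TRUE) {
  if (prior < 0 || prior > 1) stop("prior must be in [0, 1]")
  if (sensitivity <= 0 || sensitivity > 1 || specificity <= 0 || specificity > 1)
    stop("sensitivity and specificity must be in (0, 1]")
  if (prior == 0) return(0)
  if (prior == 1) return(1)
  if (classified_positive && specificity == 1) {
    warning("specificity 1 with a positive call: posterior is 1")
    return(1)
  }
  lr <- if (classified_positive) sensitivity / (1 - specificity)
        else (1 - sensitivity) / specificity
  odds <- prior / (1 - prior) * lr
  odds / (1 + odds)
}

#' Classify second-year migration as continuous or stable
#'
#' Patient-level screening classification: the unsigned migration over the
#' second postoperative year (the 12-to-24-month interval migration) is
#' compared against a study-chosen threshold. No default threshold is
#' provided -- it is a study design parameter. Missing interval data yields
#' `"indeterminate"`.
#'
#' @param interval A `migration_result` for the second-year interval (from
#'   [interval_migration()]), or the unsigned outcome value itself, or `NA`.
#' @param threshold Classification threshold (mm); migration strictly above
#'   it is `"continuous"`.
#' @param outcome `"mtpm"` or `"tt"`.
#' @return `"continuous"`, `"stable"`, or `"indeterminate"`.
#' @export
classify_migration <- function(interval, threshold, outcome = c("mtpm", "tt")) {
  outcome <- match.arg(outcome)
  if (missing(threshold) || !is.finite(threshold) || threshold <= 0)
    stop("a positive classification threshold must be chosen by the study")
  value <- if (inherits(interval, "migration_result")) interval[[outcome]]
           else suppressWarnings(as.numeric(interval))
  if (is.null(value) || length(value) != 1L || !is.finite(value))
    return("indeterminate")
  if (value > threshold) "continuous" else "stable"
}
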