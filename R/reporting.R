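#' Analyze a study: compute all migrations with exclusion accounting
#'
#' Runs [compute_migration()] for every follow-up (and double) examination
#' of every patient against that patient's baseline, converting left-sided
#' results to the right-side convention before any aggregation. Failures
#' (e.g. too few shared markers after occlusion) do not abort the analysis;
#' they are recorded as exclusions for the flow report.
#'
#' @param study A `synthetic_study` from [gen_study()], or a list with
#'   `manifest` and `exams` in the same layout.
#' @param marker_method `"all"` or `"consistent"` (see [select_markers()]).
#' @param cs A [coordinate_system_spec()].
#' @return List: `results` (a [results_table()] data.frame with `group`,
#'   `timepoint` and `kind` columns added), `exclusions` (data.frame
#'   `patient_id`, `exam_id`, `timepoint`, `kind`, `reason`).
#' @export
analyze_study <- function(study, marker_method = c("all", "consistent"),
                          cs = coordinate_system_spec()) {
  marker_method <- match.arg(marker_method)
  res <- list(); excl <- list()
  kinds <- vapply(study$exams, function(e) e$kind, character(1))
  pids <- vapply(study$exams, function(e) e$patient_id, character(1))
  for (pid in unique(pids)) {
    ids <- names(study$exams)[pids == pid]
    base_id <- ids[kinds[ids] == "baseline"]
    if (length(base_id) != 1L) next
    baseline <- study$exams[[base_id]]
    fu_ids <- ids[kinds[ids] != "baseline"]
    selection <- NULL
    if (marker_method == "consistent" && length(fu_ids)) {
      sel_try <- try({
        fus <- study$exams[fu_ids]
        list(reference = select_markers(baseline, fus, "bone", "consistent")[[1]],
             migrating = select_markers(baseline, fus, "prosthesis", "consistent")[[1]])
      }, silent = TRUE)
      if (!inherits(sel_try, "try-error")) selection <- sel_try
    }
    for (fid in fu_ids) {
      fu <- study$exams[[fid]]
      r <- try(compute_migration(baseline, fu, cs = cs,
                                 marker_method = marker_method,
                                 marker_selection = selection),
               silent = TRUE)
      grp <- if (!is.null(fu$meta$group)) fu$meta$group else NA_character_
      if (inherits(r, "try-error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          patient_id = pid, exam_id = fid, timepoint = fu$days_since_surgery,
          kind = fu$kind, reason = "occlusion",
          detail = conditionMessage(attr(r, "condition")))
        next
      }
      r <- to_right_side(r)
      row <- results_table(r)
      row$group <- grp
      row$kind <- fu$kind
      res[[length(res) + 1L]] <- row
    }
  }
  results <- if (length(res)) do.call(rbind, res) else NULL
  if (!is.null(results)) {
    tps <- study$scenario$timepoints
    if (!is.null(tps))
      results$timepoint <- vapply(results$days, function(d)
        tps[which.min(abs(tps - d))], numeric(1))
  }
  list(results = results,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(patient_id = character(), exam_id = character(),
                                    timepoint = numeric(), kind = character(),
                                    reason = character(), detail = character()))
}

#' Group outcome table
#'
#' Per outcome x timepoint x group summary of the (explicitly chosen,
#' concise or complete) results: n plus mean and 95% CI of the mean
#' (t-distribution), mean and SD, or median and IQR for non-normal data.
#' For two-group designs the between-group difference with its 95% CI
#' (Welch) is appended. Empty cells are reported with n = 0, not dropped;
#' single-observation cells carry the value with no dispersion and a
#' warning.
#'
#' @param results Results data.frame with `group` and `timepoint` columns
#'   (e.g. `analyze_study()$results`, after [qc_gate()] selection).
#' @param outcomes Outcome columns to summarize.
#' @param style `"mean_ci"`, `"mean_sd"`, or `"median_iqr"`.
#' @param conf_level Confidence level for CIs.
#' @return data.frame of class `outcome_table`: `outcome`, `timepoint`,
#'   `group`, `n`, `center`, `lo`, `hi`, `dispersion_type`, `unit`; group
#'   differences (two-group designs, mean-based styles) as extra rows with
#'   `group = "difference"`.
#' @export
outcome_table <- function(results, outcomes = c("tx_mm", "ty_mm", "tz_mm",
                                                "rx_deg", "ry_deg", "rz_deg",
                                                "mtpm_mm"),
                          style = c("mean_ci", "mean_sd", "median_iqr"),
                          conf_level = 0.95) {
  style <- match.arg(style)
  stopifnot(is.data.frame(results), all(c("group", "timepoint") %in% names(results)))
  groups <- sort(unique(results$group))
  tps <- sort(unique(results$timepoint))
  out <- list(); warn <- character()
  for (oc in outcomes) {
    for (tp in tps) {
      for (g in groups) {
        x <- results[[oc]][results$group == g & results$timepoint == tp]
        x <- x[is.finite(x)]
        n <- length(x)
        cell <- data.frame(outcome = oc, timepoint = tp, group = g, n = n,
                           center = NA_real_, lo = NA_real_, hi = NA_real_,
                           dispersion_type = style,
                           unit = if (grepl("_deg$", oc)) "deg" else "mm")
        if (n >= 1L) {
          if (style == "median_iqr") {
            cell$center <- stats::median(x)
            cell$lo <- stats::quantile(x, 0.25, names = FALSE)
            cell$hi <- stats::quantile(x, 0.75, names = FALSE)
          } else {
            cell$center <- mean(x)
            if (n >= 2L) {
              s <- stats::sd(x)
              if (style == "mean_ci") {
                half <- stats::qt(1 - (1 - conf_level) / 2, n - 1L) * s / sqrt(n)
                cell$lo <- cell$center - half; cell$hi <- cell$center + half
              } else {
                cell$lo <- s; cell$hi <- s
              }
            } else {
              warn <- c(warn, sprintf("%s, timepoint %g, group %s: single result, no dispersion",
                                      oc, tp, g))
            }
          }
        }
        out[[length(out) + 1L]] <- cell
      }
      if (length(groups) == 2L && style != "median_iqr") {
        xa <- results[[oc]][results$group == groups[1] & results$timepoint == tp]
        xb <- results[[oc]][results$group == groups[2] & results$timepoint == tp]
        xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
        if (length(xa) >= 2L && length(xb) >= 2L) {
          tt <- stats::t.test(xa, xb, conf.level = conf_level)
          out[[length(out) + 1L]] <- data.frame(
            outcome = oc, timepoint = tp, group = "difference",
            n = length(xa) + length(xb),
            center = unname(diff(rev(tt$estimate))),
            lo = tt$conf.int[1], hi = tt$conf.int[2],
            dispersion_type = "mean_ci",
            unit = if (grepl("_deg$", oc)) "deg" else "mm")
        }
      }
    }
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("outcome_table", class(tab))
  attr(tab, "warnings") <- warn
  tab
}

# Stable checklist item registry. Items mirror the reporting checklist for
# migration studies; ids are stable across releases.
checklist_items <- function() {
  it <- function(id, section, item, derivable = FALSE)
    data.frame(id = id, section = section, item = item, derivable = derivable)
  rbind(
    it("title.rsa_identified", "Title and abstract",
       "Study identified as RSA or CT-RSA in the title"),
    it("abstract.rsa_identified", "Title and abstract",
       "Study identified as RSA or CT-RSA in abstract and keywords"),
    it("methods.prior_reports", "Study details",
       "References to prior or partial results of the same cohort"),
    it("methods.inclusion_period", "Study details",
       "First and last inclusion dates"),
    it("methods.site", "Study details",
       "Country and hospital(s) where surgeries were performed"),
    it("methods.surgeons", "Study details",
       "Number of surgeons and surgeries per surgeon"),
    it("methods.prosthesis_description", "Study groups",
       "Prosthesis, cement/coating and liner characteristics per group"),
    it("followup.first_exam_loading", "Follow-up",
       "Whether the baseline examination preceded weightbearing", TRUE),
    it("followup.baseline_timing", "Follow-up",
       "Mean and SD of days from surgery to baseline examination", TRUE),
    it("followup.endpoint_timing", "Follow-up",
       "Mean and SD of days from surgery to primary endpoint examination", TRUE),
    it("technique.method", "RSA technique",
       "Migration measurement method (marker-based, model-based, CT-RSA)", TRUE),
    it("technique.patient_position", "RSA technique",
       "Patient position during examination (supine, weightbearing)", TRUE),
    it("technique.software", "RSA technique",
       "Analysis software and version"),
    it("technique.coordinate_system", "RSA technique",
       "Location and orientation of the migration coordinate system", TRUE),
    it("technique.fictive_points", "RSA technique",
       "Use of fictive/feature points for MTPM", TRUE),
    it("technique.detector", "Marker-/model-based RSA technique",
       "Detector image resolution (DPI) and type", TRUE),
    it("technique.markers", "Marker-/model-based RSA technique",
       "Marker material and size"),
    it("technique.cage", "Marker-/model-based RSA technique",
       "Calibration cage and type (uniplanar, biplanar)", TRUE),
    it("technique.cutoffs", "Marker-/model-based RSA technique",
       "Condition-number and mean-error cut-off values", TRUE),
    it("technique.marker_method", "Marker-/model-based RSA technique",
       "Consistent- or all-marker analysis method", TRUE),
    it("ct.scanner", "CT-RSA technique", "CT scanner brand and model"),
    it("ct.acquisition", "CT-RSA technique",
       "Voxel size, slice thickness, kV, mAs"),
    it("ct.mar", "CT-RSA technique", "Whether metal artifact reduction was used"),
    it("ct.dose", "CT-RSA technique", "Effective radiation dose (mSv)"),
    it("results.flow_counts", "Study flow",
       "Examinations per group and timepoint in the primary analysis", TRUE),
    it("results.flow_missing", "Study flow",
       "Counts of and reasons for missing/excluded examinations", TRUE),
    it("results.units", "Outcome",
       "Migration reported in mm (translations) and degrees (rotations)", TRUE),
    it("results.double_exam_table", "Outcome",
       "Double-examination mean, SD and n per outcome and group", TRUE),
    it("results.quality_summary", "Outcome",
       "Mean and SD of marker count, CN and ME per body at the primary timepoint", TRUE),
    it("results.outcome_table", "Outcome",
       "Raw migration per group and timepoint: mean with CI or SD, or median/IQR", TRUE),
    it("revisions.counts", "Revisions/failures",
       "Revisions/failures per group with reasons"),
    it("revisions.last_migration", "Revisions/failures",
       "Migration at last follow-up before revision/failure"))
}

#' Checklist compliance report
#'
#' Fills the study reporting checklist: items derivable from the supplied
#' study and results (timing statistics, marker-count / CN / ME summaries
#' at the primary timepoint, flow accounting, threshold configuration) are
#' computed; the remainder are taken from `config` entries keyed by item
#' id, and flagged `missing` when absent. The item identifiers are stable.
#'
#' @param study A `synthetic_study` (or list with `manifest`, `exams`).
#' @param results Optional results data.frame from [analyze_study()].
#' @param config Named list of manually supplied item values (names are
#'   checklist item ids, e.g. `technique.software = "rsakit 0.1.0"`).
#' @param thresholds A [qc_thresholds()] list (fills the cut-off item).
#' @param primary_timepoint Day of the primary endpoint (default: last
#'   protocol timepoint).
#' @return data.frame of class `checklist_report`: `id`, `section`, `item`,
#'   `status` (`"provided"`/`"missing"`), `value`.
#' @export
checklist_report <- function(study, results = NULL, config = list(),
                             thresholds = qc_thresholds(),
                             primary_timepoint = NULL) {
  items <- checklist_items()
  if (is.null(primary_timepoint) && !is.null(study$scenario$timepoints))
    primary_timepoint <- max(study$scenario$timepoints)
  exams <- study$exams
  kinds <- vapply(exams, function(e) e$kind, character(1))
  days <- vapply(exams, function(e) e$days_since_surgery, numeric(1))
  fmt_ms <- function(x) sprintf("mean %.1f, SD %.1f days (n = %d)",
                                mean(x), stats::sd(x), length(x))
  value <- character(nrow(items)); status <- rep("missing", nrow(items))
  set_item <- function(id, v) {
    i <- match(id, items$id)
    value[i] <<- v; status[i] <<- "provided"
  }
  base_days <- days[kinds == "baseline"]
  if (length(base_days)) set_item("followup.baseline_timing", fmt_ms(base_days))
  if (!is.null(primary_timepoint)) {
    ep <- days[kinds == "followup" &
                 abs(days - primary_timepoint) <= 0.2 * primary_timepoint]
    if (length(ep)) set_item("followup.endpoint_timing", fmt_ms(ep))
  }
  wb <- unique(vapply(exams[kinds == "baseline"],
                      function(e) e$weightbearing, character(1)))
  if (length(wb)) set_item("followup.first_exam_loading", paste(wb, collapse = ", "))
  mods <- unique(vapply(exams, function(e) e$modality, character(1)))
  set_item("technique.method", paste0("marker-based ", paste(mods, collapse = "/")))
  set_item("technique.patient_position",
           paste(unique(vapply(exams, function(e) e$weightbearing, character(1))),
                 collapse = ", "))
  set_item("technique.coordinate_system",
           "origin at baseline geometric center of the migrating body; X medial, Y superior, Z anterior (right-side convention)")
  set_item("technique.cutoffs",
           sprintf("ME <= %g mm; CN <= %g (%s)", thresholds$me_max,
                   thresholds$cn_max, thresholds$cn_scaling))
  dpis <- unlist(lapply(exams, function(e) e$meta$dpi))
  if (length(dpis)) set_item("technique.detector", sprintf("%g DPI (digital)", min(dpis)))
  has_fict <- any(vapply(exams, function(e)
    !is.null(e$bodies$prosthesis$fictive), logical(1)))
  set_item("technique.fictive_points",
           if (has_fict) "fictive points included in the MTPM point set"
           else "no fictive points; MTPM over prosthesis markers")
  if (!is.null(results) && nrow(results)) {
    set_item("technique.marker_method",
             paste(unique(results$marker_method), collapse = ", "))
    set_item("results.units", "mm (translations), degrees (rotations)")
    set_item("results.flow_counts",
             sprintf("%d analyzed migrations over %d timepoints",
                     nrow(results), length(unique(results$timepoint))))
    if (!is.null(primary_timepoint)) {
      pr <- results[results$timepoint == primary_timepoint, , drop = FALSE]
      if (nrow(pr) >= 2L)
        set_item("results.quality_summary", sprintf(
          "reference body: markers %.1f (SD %.1f), CN %.0f (SD %.0f), ME %.3f (SD %.3f) mm; migrating body: markers %.1f (SD %.1f), CN %.1f (SD %.1f), ME %.3f (SD %.3f) mm",
          mean(pr$n_markers_ref), stats::sd(pr$n_markers_ref),
          mean(pr$cn_ref), stats::sd(pr$cn_ref),
          mean(pr$me_ref_mm), stats::sd(pr$me_ref_mm),
          mean(pr$n_markers_mov), stats::sd(pr$n_markers_mov),
          mean(pr$cn_mov), stats::sd(pr$cn_mov),
          mean(pr$me_mov_mm), stats::sd(pr$me_mov_mm)))
    }
  }
  for (id in names(config))
    if (id %in% items$id) set_item(id, as.character(config[[id]]))
  out <- data.frame(items[, c("id", "section", "item")],
                    status = status, value = value)
  class(out) <- c("checklist_report", class(out))
  out
}

#' @export
format.checklist_report <- function(x, ...) {
  lines <- c("# Reporting checklist", "")
  for (sec in unique(x$section)) {
    lines <- c(lines, paste0("## ", sec), "")
    sub <- x[x$section == sec, ]
    lines <- c(lines, sprintf("- [%s] %s%s",
                              ifelse(sub$status == "provided", "x", " "),
                              sub$item,
                              ifelse(sub$value != "", paste0(": ", sub$value), "")),
               "")
  }
  paste(lines, collapse = "\n")
}

#' Study flow report
#'
#' CONSORT/STROBE-style accounting per group and timepoint: expected
#' examinations (from the manifest and protocol), analyzed examinations,
#' and missing ones broken down by reason (occlusion, quality-gate
#' exclusion, out-of-window, dropout, other). The conservation invariant
#' `expected = analyzed + missing` holds on every run, and reason counts
#' sum to `missing`.
#'
#' @param study A `synthetic_study`.
#' @param results Concise (post-gate) results data.frame used in the
#'   primary analysis.
#' @param exclusions Exclusion records from [analyze_study()] (reason
#'   `occlusion`) to which QC-gate exclusions may be appended.
#' @param qc Optional [qc_gate()] output; its `reasons` become
#'   `quality_gate` exclusions.
#' @return data.frame of class `flow_report`: `group`, `timepoint`,
#'   `expected`, `analyzed`, `missing`, one column per reason.
#' @export
flow_report <- function(study, results, exclusions = NULL, qc = NULL) {
  tps <- study$scenario$timepoints
  manifest <- study$manifest
  reasons <- c("occlusion", "quality_gate", "out_of_window", "dropout", "other")
  rec <- list()
  excl_tab <- data.frame(exam_id = character(), patient_id = character(),
                         timepoint = numeric(), reason = character())
  if (!is.null(exclusions) && nrow(exclusions)) {
    e <- exclusions
    e$timepoint <- vapply(e$timepoint, function(d) tps[which.min(abs(tps - d))],
                          numeric(1))
    excl_tab <- rbind(excl_tab, e[, c("exam_id", "patient_id", "timepoint", "reason")])
  }
  if (!is.null(qc) && nrow(qc$reasons)) {
    q <- unique(qc$reasons[, c("exam_id", "patient_id")])
    q$timepoint <- NA_real_
    for (i in seq_len(nrow(q))) {
      d <- qc$complete$days[qc$complete$exam_id == q$exam_id[i]][1]
      q$timepoint[i] <- tps[which.min(abs(tps - d))]
    }
    q$reason <- "quality_gate"
    excl_tab <- rbind(excl_tab, q)
  }
  for (g in unique(manifest$group)) {
    pids <- manifest$patient_id[manifest$group == g]
    for (tp in tps) {
      # expected = enrolled patients not yet dropped out at this timepoint
      dropped <- !is.na(manifest$dropout_day[manifest$group == g]) &
        manifest$dropout_day[manifest$group == g] < tp
      expected <- length(pids)
      analyzed <- sum(results$group == g & results$timepoint == tp &
                        results$kind == "followup", na.rm = TRUE)
      cnt <- setNames(numeric(length(reasons)), reasons)
      cnt["dropout"] <- sum(dropped)
      sub <- excl_tab[excl_tab$patient_id %in% pids & excl_tab$timepoint == tp &
                        !grepl("_dbl$", excl_tab$exam_id), , drop = FALSE]
      for (r in unique(sub$reason)) {
        key <- if (r %in% reasons) r else "other"
        cnt[key] <- cnt[key] + sum(sub$reason == r)
      }
      missing <- expected - analyzed
      accounted <- sum(cnt)
      if (accounted < missing) cnt["other"] <- cnt["other"] + (missing - accounted)
      # a single exam can trip several processes (e.g. dropout after an
      # occlusion): clip so reason counts sum exactly to missing
      for (r in c("other", "dropout", "out_of_window", "quality_gate", "occlusion")) {
        over <- sum(cnt) - missing
        if (over <= 0) break
        cnt[r] <- max(0, cnt[r] - over)
      }
      rec[[length(rec) + 1L]] <- data.frame(group = g, timepoint = tp,
                                            expected = expected,
                                            analyzed = analyzed,
                                            missing = missing, t(cnt))
    }
  }
  out <- do.call(rbind, rec)
  class(out) <- c("flow_report", class(out))
  out
}
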