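assessment_row_to_obj <- function(row) {
  vtt_assessment(row$side, row$tip_landmark, row$tip_distance_mm,
                 row$timepoint)
}

lengths_row_to_obj <- function(row) {
  vtt_lengths(row$rv_mm, row$ivc_above_mm, row$ivc_below_mm)
}

# per-patient endpoint rows: baseline + follow-up with week-3 fallback
patient_rows <- function(assessments, id) {
  rows <- assessments[assessments$patient_id == id, , drop = FALSE]
  base <- rows[rows$timepoint == "baseline", , drop = FALSE]
  wk9 <- rows[rows$timepoint == "week9", , drop = FALSE]
  wk3 <- rows[rows$timepoint == "week3", , drop = FALSE]
  fu <- if (nrow(wk9)) wk9[1, , drop = FALSE]
        else if (nrow(wk3)) wk3[1, , drop = FALSE]
  list(baseline = if (nrow(base)) base[1, , drop = FALSE],
       followup = fu,
       week3 = if (nrow(wk3)) wk3[1, , drop = FALSE],
       week9 = if (nrow(wk9)) wk9[1, , drop = FALSE],
       fallback = nrow(wk9) == 0L && nrow(wk3) > 0L)
}

eligible_evaluable_ids <- function(patients) {
  patients$patient_id[patients$dosed & !patients$central_review_excluded]
}

#' Derive the primary Mayo-improvement endpoint and its inference
#'
#' Classifies each eligible-and-evaluable patient as improved, stable or
#' worsened between baseline and week 9 (falling back to the week-3 scan
#' when the week-9 scan is missing; patients with neither follow-up scan
#' are non-evaluable and reported as missing, never imputed), applies the
#' two-stage decision rule (success when the improved count exceeds the
#' rejection boundary `r`) and computes design-adjusted inference at the
#' null response rate.
#'
#' @param cohort A `vtt_cohort`.
#' @param design A [two_stage_design()].
#' @param p0 Null response probability.
#' @param conf_level Two-sided confidence level for the interval.
#' @return A list with `counts` (improved / stable / worsened /
#'   non_evaluable), `n_evaluable`, `proportion` (improved over
#'   evaluable, percent to 1 dp), `success`, `inference` (an
#'   `inference_result`) and `deviations` (character log).
#' @export
derive_primary <- function(cohort, design = two_stage_design(0, 13, 2, 20),
                           p0 = 0.05, conf_level = 0.80) {
  design <- as_two_stage_design(design)
  validate_cohort(cohort)
  ids <- eligible_evaluable_ids(cohort$patients)
  if (length(ids) == 0L)
    stop("no eligible-and-evaluable patients in the cohort", call. = FALSE)
  status <- character(0); deviations <- character(0)
  for (id in ids) {
    pr <- patient_rows(cohort$assessments, id)
    if (is.null(pr$baseline) || is.null(pr$followup)) {
      status[id] <- "non_evaluable"
      deviations <- c(deviations, sprintf(
        "%s: no %s scan; non-evaluable for the Mayo endpoint", id,
        if (is.null(pr$baseline)) "baseline" else "follow-up"))
      next
    }
    if (pr$fallback)
      deviations <- c(deviations, sprintf(
        "%s: week-9 scan missing; week-3 scan used", id))
    status[id] <- mayo_improvement(assessment_row_to_obj(pr$baseline),
                                   assessment_row_to_obj(pr$followup))
  }
  counts <- c(improved = sum(status == "improved"),
              stable = sum(status == "stable"),
              worsened = sum(status == "worsened"),
              non_evaluable = sum(status == "non_evaluable"))
  n_eval <- length(ids)
  infer_design <- design
  if (n_eval != design$n) {
    if (n_eval > design$n1) {
      infer_design <- two_stage_design(design$r1, design$n1,
                                       min(design$r, n_eval), n_eval)
      deviations <- c(deviations, sprintf(
        "attained sample size %d differs from planned %d; inference uses planned stage 1 with attained stage-2 size",
        n_eval, design$n))
    } else {
      deviations <- c(deviations, sprintf(
        "attained sample size %d does not exceed the planned stage-1 size %d; inference uses the planned design",
        n_eval, design$n1))
    }
  }
  x <- unname(counts["improved"])
  list(counts = counts,
       n_evaluable = n_eval,
       proportion = pct1(x, n_eval),
       success = x > design$r,
       inference = design_inference(min(x, infer_design$n), infer_design,
                                    p0 = p0, conf_level = conf_level),
       status = status,
       deviations = deviations)
}

median_range <- function(x) {
  if (length(x) == 0L)
    return(list(n = 0L, median = NA_real_, min = NA_real_, max = NA_real_))
  list(n = length(x), median = stats::median(x), min = min(x), max = max(x))
}

#' Derive the secondary endpoints
#'
#' Per-timepoint percent change in thrombus length (median and range over
#' patients with that scan), thrombus partial response (>30 percent
#' reduction, among patients with a week-9 scan), the count of patients
#' with any length reduction at their endpoint timepoint (week 9, or
#' week 3 when week 9 is missing), the RECIST v1.1 response table at
#' week 9 (nadir taken as the smallest sum up to the timepoint) and the
#' change in surgical extent among operated patients.
#'
#' @inheritParams derive_primary
#' @return A nested list; percentages are reported to 1 dp.
#' @export
derive_secondary <- function(cohort) {
  validate_cohort(cohort)
  ids <- eligible_evaluable_ids(cohort$patients)
  pct <- list(week3 = numeric(0), week9 = numeric(0))
  any_reduction <- 0L; n_change_eval <- 0L
  vtt_pr <- 0L; n_week9 <- 0L
  recist <- c(CR = 0L, PR = 0L, SD = 0L, PD = 0L, missing = 0L)
  for (id in ids) {
    pr <- patient_rows(cohort$assessments, id)
    if (is.null(pr$baseline)) next
    s0 <- vtt_sum(lengths_row_to_obj(pr$baseline))
    for (tp in c("week3", "week9")) {
      if (!is.null(pr[[tp]]) && s0 > 0)
        pct[[tp]] <- c(pct[[tp]],
                       stats::setNames(vtt_percent_change(
                         s0, vtt_sum(lengths_row_to_obj(pr[[tp]]))), id))
    }
    if (!is.null(pr$followup) && s0 > 0) {
      n_change_eval <- n_change_eval + 1L
      chg <- vtt_percent_change(s0, vtt_sum(lengths_row_to_obj(pr$followup)))
      if (chg > 0) any_reduction <- any_reduction + 1L
    }
    if (!is.null(pr$week9) && s0 > 0) {
      n_week9 <- n_week9 + 1L
      chg9 <- vtt_percent_change(s0, vtt_sum(lengths_row_to_obj(pr$week9)))
      if (vtt_response(chg9) == "VTT_PR") vtt_pr <- vtt_pr + 1L
    }
    # RECIST at week 9 from target-lesion sums
    b <- pr$baseline$target_sum_mm
    if (!is.null(pr$week9) && !is.na(pr$week9$target_sum_mm) && !is.na(b)) {
      nadir <- min(b, if (!is.null(pr$week3)) pr$week3$target_sum_mm else b,
                   na.rm = TRUE)
      cls <- recist_classify(b, pr$week9$target_sum_mm, nadir,
                             pr$week9$new_lesion)
      recist[cls] <- recist[cls] + 1L
    } else {
      recist["missing"] <- recist["missing"] + 1L
    }
  }
  # surgical change among patients with planned and performed records
  s <- cohort$surgery
  surg_counts <- c(less_extensive = 0L, unchanged = 0L, more_extensive = 0L)
  operated <- character(0)
  for (id in unique(s$patient_id)) {
    pl <- s[s$patient_id == id & s$phase == "planned", , drop = FALSE]
    pf <- s[s$patient_id == id & s$phase == "performed", , drop = FALSE]
    if (nrow(pl) == 0L || nrow(pf) == 0L) next
    operated <- c(operated, id)
    chg <- surgical_change(
      surgical_plan(pl$approach[1], pl$level_of_control[1],
                    pl$incision_rank[1]),
      surgical_plan(pf$approach[1], pf$level_of_control[1],
                    pf$incision_rank[1]))
    surg_counts[chg$change] <- surg_counts[chg$change] + 1L
  }
  list(
    vtt_length_change = list(
      week3 = median_range(pct$week3),
      week9 = median_range(pct$week9),
      any_reduction = list(n = any_reduction, denom = n_change_eval,
                           percent = pct1(any_reduction, n_change_eval))),
    vtt_pr = list(n = vtt_pr, denom = n_week9,
                  percent = pct1(vtt_pr, n_week9)),
    recist_week9 = as.list(recist),
    surgical = list(counts = as.list(surg_counts),
                    n_operated = length(operated),
                    percent_less_extensive =
                      pct1(surg_counts[["less_extensive"]],
                           length(operated))))
}

#' CONSORT population accounting
#'
#' Intention-to-treat is every registered participant; the safety and
#' evaluable populations are participants who received at least one dose
#' of study drug; the eligible-and-evaluable population removes patients
#' excluded on central review.
#'
#' @param patients The `patients` table of a cohort (columns
#'   `registered`, `dosed`, `central_review_excluded`).
#' @return A list of population counts.
#' @export
consort_accounting <- function(patients) {
  list(itt = sum(patients$registered),
       safety = sum(patients$dosed),
       evaluable = sum(patients$dosed),
       eligible_evaluable = sum(patients$dosed &
                                  !patients$central_review_excluded))
}

#' Summarise adverse events by term and maximum grade
#'
#' Restricted to treatment-related events; each patient contributes once
#' per term at their maximum recorded grade. Reports, per term, the
#' number and percentage of patients with an event of any grade and with
#' grade 3 or higher, filtered to terms affecting at least `min_fraction`
#' of patients.
#'
#' @param ae The `ae` table (columns `patient_id`, `term`, `grade` 1-5,
#'   `related`).
#' @param n_patients Denominator for the percentages.
#' @param min_fraction Minimum fraction of patients with the term for it
#'   to be reported (default 0.10).
#' @return A data frame with columns `term`, `n_any`, `pct_any`,
#'   `n_grade3plus`, `pct_grade3plus`, sorted by decreasing frequency.
#' @export
ae_summary <- function(ae, n_patients, min_fraction = 0.10) {
  if (nrow(ae) && any(!ae$grade %in% 1:5))
    stop("adverse event grades must be integers 1-5", call. = FALSE)
  out <- data.frame(term = character(), n_any = integer(),
                    pct_any = numeric(), n_grade3plus = integer(),
                    pct_grade3plus = numeric(), stringsAsFactors = FALSE)
  rel <- ae[ae$related, , drop = FALSE]
  if (nrow(rel) == 0L) return(out)
  mx <- stats::aggregate(grade ~ patient_id + term, data = rel, FUN = max)
  for (term in sort(unique(mx$term))) {
    sub <- mx[mx$term == term, , drop = FALSE]
    n_any <- nrow(sub)
    if (n_any / n_patients < min_fraction) next
    n_g3 <- sum(sub$grade >= 3)
    out <- rbind(out, data.frame(
      term = term, n_any = n_any, pct_any = pct1(n_any, n_patients),
      n_grade3plus = n_g3, pct_grade3plus = pct1(n_g3, n_patients),
      stringsAsFactors = FALSE))
  }
  out[order(-out$n_any, out$term), , drop = FALSE]
}

default_trial_config <- function() {
  list(design = list(r1 = 0, n1 = 13, r = 2, n = 20),
       p0 = 0.05, conf_level = 0.80, ae_min_fraction = 0.10)
}

#' Run the full trial analysis
#'
#' Orchestrates the pipeline: read the cohort CSVs, validate them, derive
#' the primary and secondary endpoints, apply the two-stage decision rule
#' and design-adjusted inference, compute CONSORT accounting and the
#' adverse-event table, and return (optionally serialise) the trial
#' report. Deterministic for fixed inputs; every fallback or protocol
#' deviation is logged in the report.
#'
#' @param cohort A `vtt_cohort`, or a directory path readable by
#'   [read_cohort()].
#' @param config A list with elements `design` (list with `r1`, `n1`,
#'   `r`, `n`), `p0`, `conf_level` and `ae_min_fraction`, or a path to a
#'   YAML file with those fields; missing fields take the trial defaults
#'   (design 0/13, 2/20; p0 0.05; 80 percent confidence).
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return An object of class `trial_report`.
#' @examples
#' rep <- run_trial_analysis(reference_cohort())
#' rep$primary$counts
#' @export
run_trial_analysis <- function(cohort, config = list(), out = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_trial_config(), config)
  design <- as_two_stage_design(cfg$design)
  validate_cohort(cohort)
  consort <- consort_accounting(cohort$patients)
  primary <- derive_primary(cohort, design, p0 = cfg$p0,
                            conf_level = cfg$conf_level)
  secondary <- derive_secondary(cohort)
  aes <- ae_summary(cohort$ae, n_patients = consort$eligible_evaluable,
                    min_fraction = cfg$ae_min_fraction)
  report <- structure(list(
    config = list(design = unclass(design)[c("r1", "n1", "r", "n")],
                  p0 = cfg$p0, conf_level = cfg$conf_level,
                  ae_min_fraction = cfg$ae_min_fraction),
    consort = consort,
    primary = list(
      counts = as.list(primary$counts),
      n_evaluable = primary$n_evaluable,
      percent_improved = primary$proportion,
      success = primary$success,
      inference = list(
        estimate = primary$inference$estimate,
        estimate_percent = round_half_up(100 * primary$inference$estimate,
                                         1),
        umvue = primary$inference$umvue,
        ci_lower = primary$inference$ci_lower,
        ci_upper = primary$inference$ci_upper,
        ci_percent = c(round_half_up(100 * primary$inference$ci_lower, 1),
                       round_half_up(100 * primary$inference$ci_upper, 1)),
        conf_level = primary$inference$conf_level,
        p_value = primary$inference$p_value)),
    secondary = secondary,
    ae_table = aes,
    deviations = primary$deviations), class = "trial_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Serialise a trial report to JSON
#'
#' @param report A `trial_report`.
#' @param path Output file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "trial_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Trial analysis report\n")
  cat(sprintf("  populations: ITT %d | evaluable %d | eligible-and-evaluable %d\n",
              x$consort$itt, x$consort$evaluable,
              x$consort$eligible_evaluable))
  cc <- x$primary$counts
  cat(sprintf("  primary: %d/%d improved (%.1f%%), %d stable, %d worsened, %d non-evaluable; trial %s\n",
              cc$improved, x$primary$n_evaluable, x$primary$percent_improved,
              cc$stable, cc$worsened, cc$non_evaluable,
              if (x$primary$success) "SUCCESS" else "NOT successful"))
  inf <- x$primary$inference
  cat(sprintf("  inference: estimate %.1f%% [%.0f%% CI %.1f%%, %.1f%%], p = %s vs p0 = %g\n",
              inf$estimate_percent, 100 * inf$conf_level, inf$ci_percent[1],
              inf$ci_percent[2], format(signif(inf$p_value, 4)), x$config$p0))
  sec <- x$secondary
  cat(sprintf("  VTT length: %d/%d (%.1f%%) any reduction; VTT-PR %d/%d (%.1f%%)\n",
              sec$vtt_length_change$any_reduction$n,
              sec$vtt_length_change$any_reduction$denom,
              sec$vtt_length_change$any_reduction$percent,
              sec$vtt_pr$n, sec$vtt_pr$denom, sec$vtt_pr$percent))
  r <- sec$recist_week9
  cat(sprintf("  RECIST week 9: CR %d | PR %d | SD %d | PD %d | missing %d\n",
              r$CR, r$PR, r$SD, r$PD, r$missing))
  cat(sprintf("  surgery: %d/%d (%.1f%%) less extensive than planned\n",
              sec$surgical$counts$less_extensive, sec$surgical$n_operated,
              sec$surgical$percent_less_extensive))
  if (length(x$deviations))
    cat("  deviations:\n", paste0("    - ", x$deviations, "\n"), sep = "")
  invisible(x)
}
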