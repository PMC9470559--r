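#' @name vtt-enums
#' @title Controlled vocabularies for VTT assessments
#' @description
#' Anatomical landmarks of the thrombus tip, ordered caudad to craniad:
#' `rv_branches` < `rv_lateral_to_gonadal` (left kidney only) < `rv_main`
#' < `ivc` < `ivc_hepatic_below_diaphragm` < `ivc_above_diaphragm`.
#' An `ivc` landmark additionally requires the tip distance above the
#' renal-vein ostium in mm. Timepoints are `baseline`, `week3`, `week9`.
#' @keywords internal
NULL

TIP_LANDMARKS <- c("rv_branches", "rv_lateral_to_gonadal", "rv_main",
                   "ivc", "ivc_hepatic_below_diaphragm",
                   "ivc_above_diaphragm")
TIMEPOINTS <- c("baseline", "week3", "week9")

#' One timepoint's anatomical assessment of a venous tumour thrombus
#'
#' @param side Kidney laterality, `"left"` or `"right"`.
#' @param tip_landmark One of the landmarks in [vtt-enums]:
#'   `rv_branches`, `rv_lateral_to_gonadal` (left side only), `rv_main`,
#'   `ivc`, `ivc_hepatic_below_diaphragm`, `ivc_above_diaphragm`.
#' @param tip_distance_mm Distance of the thrombus tip above the
#'   renal-vein ostium in mm; required when `tip_landmark = "ivc"`.
#' @param timepoint `"baseline"`, `"week3"` or `"week9"`.
#' @return An object of class `vtt_assessment`.
#' @examples
#' a <- vtt_assessment("right", "ivc", tip_distance_mm = 15)
#' classify_mayo(a)
#' @export
vtt_assessment <- function(side, tip_landmark, tip_distance_mm = NA_real_,
                           timepoint = "baseline") {
  side <- match.arg(side, c("left", "right"))
  tip_landmark <- match.arg(tip_landmark, TIP_LANDMARKS)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  if (tip_landmark == "rv_lateral_to_gonadal" && side != "left")
    stop("'rv_lateral_to_gonadal' is defined only for left-sided thrombi",
         call. = FALSE)
  if (tip_landmark == "ivc") {
    if (is.na(tip_distance_mm))
      stop("an 'ivc' landmark requires 'tip_distance_mm'", call. = FALSE)
    if (tip_distance_mm < 0)
      stop("'tip_distance_mm' must be >= 0", call. = FALSE)
  }
  structure(list(side = side, tip_landmark = tip_landmark,
                 tip_distance_mm = as.numeric(tip_distance_mm),
                 timepoint = timepoint),
            class = "vtt_assessment")
}

#' Mayo level of a thrombus assessment
#'
#' Classifies cranial extent on the 0-4 Mayo scale: level 0, thrombus
#' limited to the renal vein; level 1, into the IVC less than 2 cm above
#' the renal-vein ostium; level 2, more than 2 cm above the ostium but
#' below the hepatic veins; level 3, at or above the hepatic veins but
#' below the diaphragm; level 4, above the diaphragm. A tip at exactly
#' 2 cm (20 mm) is assigned level 2 because level 1 is defined strictly
#' below 2 cm.
#'
#' @param a A [vtt_assessment()].
#' @return Integer Mayo level 0-4.
#' @export
classify_mayo <- function(a) {
  stopifnot(inherits(a, "vtt_assessment"))
  switch(a$tip_landmark,
         rv_branches = ,
         rv_lateral_to_gonadal = ,
         rv_main = 0L,
         ivc = if (a$tip_distance_mm < 20) 1L else 2L,
         ivc_hepatic_below_diaphragm = 3L,
         ivc_above_diaphragm = 4L)
}

# sub-level rank inside Mayo level 0, caudad first (only meaningful there)
rv_rank <- function(a) match(a$tip_landmark, TIP_LANDMARKS)

#' Mayo-level improvement between two assessments
#'
#' Implements the trial's primary-endpoint rule. For a baseline Mayo level
#' of 1 or above, improvement is any reduction in Mayo level at follow-up
#' and worsening any increase. For renal-vein-only (level 0) baselines,
#' improvement is regression of the tip within the renal vein — main vein
#' to branches on the right; main vein to lateral of the gonadal-vein
#' insertion, or from lateral of the gonadal vein into the branches, on
#' the left (such regression enables minimally invasive surgery) — while
#' worsening is restricted to extension of the thrombus into the IVC;
#' movement craniad within the renal vein is reported as stable.
#'
#' @param baseline,followup [vtt_assessment()]s of the same patient and
#'   side at two timepoints.
#' @return `"improved"`, `"stable"` or `"worsened"`.
#' @export
mayo_improvement <- function(baseline, followup) {
  stopifnot(inherits(baseline, "vtt_assessment"),
            inherits(followup, "vtt_assessment"))
  if (baseline$side != followup$side)
    stop("baseline and follow-up assessments are for different sides",
         call. = FALSE)
  lvl0 <- classify_mayo(baseline)
  lvl1 <- classify_mayo(followup)
  if (lvl0 >= 1L) {
    if (lvl1 < lvl0) return("improved")
    if (lvl1 > lvl0) return("worsened")
    return("stable")
  }
  # level-0 baseline: sub-level regression within the renal vein
  if (lvl1 >= 1L) return("worsened")
  if (rv_rank(followup) < rv_rank(baseline)) return("improved")
  "stable"
}

#' Component lengths of a venous tumour thrombus
#'
#' @param rv_mm Length of renal-vein thrombus (mm).
#' @param ivc_above_mm Length of IVC thrombus above the midpoint of the
#'   renal-vein ostium (mm); 0 for renal-vein-only thrombi.
#' @param ivc_below_mm Length of IVC thrombus below the ostium midpoint
#'   (mm); 0 for renal-vein-only thrombi.
#' @return An object of class `vtt_lengths`.
#' @export
vtt_lengths <- function(rv_mm, ivc_above_mm = 0, ivc_below_mm = 0) {
  v <- c(rv_mm = rv_mm, ivc_above_mm = ivc_above_mm,
         ivc_below_mm = ivc_below_mm)
  if (any(!is.finite(v)) || any(v < 0))
    stop("thrombus component lengths must be finite and >= 0", call. = FALSE)
  structure(as.list(v), class = "vtt_lengths")
}

#' Total thrombus length
#'
#' Sum of the renal-vein component and the IVC components above and below
#' the renal-vein ostium. For renal-vein-only patients only the RV
#' component is measurable and the sum equals it.
#'
#' @param l A [vtt_lengths()].
#' @return Total length in mm.
#' @export
vtt_sum <- function(l) {
  if (!inherits(l, "vtt_lengths")) l <- do.call(vtt_lengths, as.list(l))
  l$rv_mm + l$ivc_above_mm + l$ivc_below_mm
}

#' Percent change in thrombus length
#'
#' `100 * (1 - Sum_T / Sum_0)` where `Sum_0` and `Sum_T` are the summed
#' component lengths at baseline and at the follow-up timepoint. Positive
#' values indicate shrinkage, negative values growth.
#'
#' @param baseline,followup [vtt_lengths()] at baseline and follow-up
#'   (plain non-negative numeric totals are also accepted).
#' @return Percent reduction (positive = shrinkage).
#' @export
vtt_percent_change <- function(baseline, followup) {
  s0 <- if (is.numeric(baseline) && length(baseline) == 1L) baseline
        else vtt_sum(baseline)
  st <- if (is.numeric(followup) && length(followup) == 1L) followup
        else vtt_sum(followup)
  if (s0 <= 0)
    stop("percent change is undefined for a zero baseline thrombus length",
         call. = FALSE)
  100 * (1 - st / s0)
}

#' Thrombus partial response call
#'
#' A VTT partial response is a reduction in summed thrombus length of
#' strictly more than 30 percent.
#'
#' @param percent_change Percent reduction from [vtt_percent_change()].
#' @return `"VTT_PR"` or `"no_VTT_PR"`.
#' @export
vtt_response <- function(percent_change) {
  ifelse(percent_change > 30, "VTT_PR", "no_VTT_PR")
}

#' RECIST v1.1 target-lesion response
#'
#' Classifies a timepoint from target-lesion diameter sums: CR if the
#' current sum is zero with no new lesion; PD if a new lesion appeared or
#' the sum increased by at least 20 percent from the nadir with an
#' absolute increase of at least 5 mm; PR if the sum decreased by at
#' least 30 percent from baseline; otherwise SD. Progression takes
#' precedence over response.
#'
#' @param baseline_sum,current_sum Sums of target-lesion diameters in mm
#'   at baseline and at the assessed timepoint.
#' @param nadir_sum Smallest sum recorded up to the assessed timepoint
#'   (defaults to the smaller of baseline and current).
#' @param new_lesion `TRUE` if any new lesion was recorded.
#' @return `"CR"`, `"PR"`, `"SD"` or `"PD"`.
#' @export
recist_classify <- function(baseline_sum, current_sum, nadir_sum = NULL,
                            new_lesion = FALSE) {
  if (is.null(nadir_sum)) nadir_sum <- min(baseline_sum, current_sum)
  if (any(c(baseline_sum, current_sum, nadir_sum) < 0))
    stop("lesion diameter sums must be >= 0", call. = FALSE)
  if (isTRUE(new_lesion)) return("PD")
  if (current_sum - nadir_sum >= 5 &&
      (nadir_sum == 0 || current_sum >= 1.2 * nadir_sum)) return("PD")
  if (current_sum == 0) return("CR")
  if (baseline_sum > 0 && current_sum <= 0.7 * baseline_sum) return("PR")
  "SD"
}

SURGICAL_APPROACHES <- c("open", "minimally_invasive")

#' Planned or performed surgical approach record
#'
#' @param approach `"open"` or `"minimally_invasive"`.
#' @param level_of_control Ordinal 1-6 describing how high the renal
#'   vein / IVC must be controlled: 1 thrombus milked into the RV and side
#'   clamped; 2 infrahepatic IVC clamping; 3 retrohepatic clamping below
#'   the hepatic veins; 4 retrohepatic clamping above the hepatic veins;
#'   5 suprahepatic infradiaphragmatic clamping; 6 suprahepatic
#'   supradiaphragmatic clamping.
#' @param incision_rank Ordinal extent of the incision (larger = more
#'   extensive); the label itself is free text and not interpreted.
#' @param incision Free-text incision label.
#' @param venovenous_bypass,hypothermic_cardiac_arrest,pringle Adjunct
#'   procedure flags.
#' @return An object of class `surgical_plan`.
#' @export
surgical_plan <- function(approach, level_of_control, incision_rank = 1L,
                          incision = "", venovenous_bypass = FALSE,
                          hypothermic_cardiac_arrest = FALSE,
                          pringle = FALSE) {
  approach <- match.arg(approach, SURGICAL_APPROACHES)
  if (!level_of_control %in% 1:6)
    stop("'level_of_control' must be an integer 1-6", call. = FALSE)
  if (!is.numeric(incision_rank) || incision_rank < 0)
    stop("'incision_rank' must be a non-negative ordinal", call. = FALSE)
  structure(list(approach = approach,
                 level_of_control = as.integer(level_of_control),
                 incision_rank = as.numeric(incision_rank),
                 incision = as.character(incision),
                 venovenous_bypass = isTRUE(venovenous_bypass),
                 hypothermic_cardiac_arrest = isTRUE(hypothermic_cardiac_arrest),
                 pringle = isTRUE(pringle)),
            class = "surgical_plan")
}

#' Change in extent between planned and performed surgery
#'
#' A performed operation is less extensive than planned if any of three
#' criteria moved in the favourable direction: (a) planned open surgery
#' was performed minimally invasively; (b) the venous level of control
#' performed is lower than planned; (c) the incision extent rank is lower
#' than planned. It is more extensive if any criterion moved the opposite
#' way and none improved; otherwise unchanged.
#'
#' @param planned,performed [surgical_plan()] records.
#' @return A list with `change` (`"less_extensive"`, `"unchanged"` or
#'   `"more_extensive"`) and logical per-criterion flags
#'   `approach_reduced`, `control_reduced`, `incision_reduced`,
#'   `approach_increased`, `control_increased`, `incision_increased`.
#' @export
surgical_change <- function(planned, performed) {
  stopifnot(inherits(planned, "surgical_plan"),
            inherits(performed, "surgical_plan"))
  flags <- list(
    approach_reduced = planned$approach == "open" &&
      performed$approach == "minimally_invasive",
    control_reduced = performed$level_of_control < planned$level_of_control,
    incision_reduced = performed$incision_rank < planned$incision_rank,
    approach_increased = planned$approach == "minimally_invasive" &&
      performed$approach == "open",
    control_increased = performed$level_of_control > planned$level_of_control,
    incision_increased = performed$incision_rank > planned$incision_rank)
  reduced <- flags$approach_reduced || flags$control_reduced ||
    flags$incision_reduced
  increased <- flags$approach_increased || flags$control_increased ||
    flags$incision_increased
  change <- if (reduced) "less_extensive"
            else if (increased) "more_extensive"
            else "unchanged"
  c(list(change = change), flags)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `(140 - age) * weight / (72 * serum creatinine)`, multiplied by 0.85
#' for women. Serum creatinine in mg/dL, weight in kg, result in mL/min.
#'
#' @param age Age in years (0 < age < 140).
#' @param weight Body weight in kg.
#' @param sex `"male"` or `"female"`.
#' @param serum_creatinine Serum creatinine in mg/dL.
#' @return Estimated creatinine clearance in mL/min.
#' @export
cockcroft_gault <- function(age, weight, sex, serum_creatinine) {
  sex <- match.arg(sex, c("male", "female"))
  if (age <= 0 || weight <= 0 || serum_creatinine <= 0)
    stop("age, weight and serum creatinine must be positive", call. = FALSE)
  crcl <- (140 - age) * weight / (72 * serum_creatinine)
  if (sex == "female") crcl <- crcl * 0.85
  crcl
}

#' Screen a baseline record against the trial eligibility criteria
#'
#' Applies the key criteria: age over 18; ECOG performance status below 2;
#' proteinuria acceptable by any of urinalysis below 2+, urinary protein
#' below 2 g/24 h, or protein:creatinine ratio below 200 mg/mmol; renal
#' function acceptable by serum creatinine at most 1.5 times the upper
#' limit of normal or Cockcroft-Gault clearance of at least 30 mL/min;
#' biopsy-proven clear cell histology; and, for metastatic (M1) patients,
#' MSKCC risk not poor. Criteria whose inputs are missing are reported as
#' indeterminate, not as failures.
#'
#' @param record A list (or one-row data frame) with any of the fields
#'   `age`, `ecog`, `urinalysis_protein` (ordinal 0 = negative, 1 = 1+,
#'   2 = 2+, ...), `urine_protein_g24`, `protein_creatinine_ratio`
#'   (mg/mmol), `serum_creatinine` (mg/dL), `creatinine_uln` (mg/dL),
#'   `weight`, `sex`, `biopsy_ccrcc` (logical), `m_stage` (`"M0"`/`"M1"`),
#'   `mskcc_risk` (`"favourable"`/`"intermediate"`/`"poor"`).
#' @return A list with `eligible` (logical; `TRUE` when no criterion is
#'   violated), `violated` and `indeterminate` character vectors of
#'   criterion names.
#' @export
eligibility_check <- function(record) {
  record <- as.list(record)
  get <- function(f) {
    v <- record[[f]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) NULL else v
  }
  violated <- character(0)
  indeterminate <- character(0)
  note <- function(name, ok) {
    if (is.null(ok)) indeterminate <<- c(indeterminate, name)
    else if (!ok) violated <<- c(violated, name)
  }

  age <- get("age")
  note("age_over_18", if (is.null(age)) NULL else age > 18)

  ecog <- get("ecog")
  note("ecog_below_2", if (is.null(ecog)) NULL else ecog < 2)

  ua <- get("urinalysis_protein")
  up <- get("urine_protein_g24")
  pcr <- get("protein_creatinine_ratio")
  prot <- c(if (!is.null(ua)) ua < 2,
            if (!is.null(up)) up < 2,
            if (!is.null(pcr)) pcr < 200)
  note("proteinuria", if (length(prot) == 0L) NULL else any(prot))

  scr <- get("serum_creatinine"); uln <- get("creatinine_uln")
  crit_scr <- if (!is.null(scr) && !is.null(uln)) scr <= 1.5 * uln
  crcl <- if (!is.null(scr) && !is.null(get("age")) &&
              !is.null(get("weight")) && !is.null(get("sex")))
    cockcroft_gault(get("age"), get("weight"), get("sex"), scr) >= 30
  renal <- c(crit_scr, crcl)
  note("renal_function", if (length(renal) == 0L) NULL else any(renal))

  ccrcc <- get("biopsy_ccrcc")
  note("biopsy_ccrcc", if (is.null(ccrcc)) NULL else isTRUE(ccrcc))

  m <- get("m_stage")
  if (is.null(m)) {
    indeterminate <- c(indeterminate, "mskcc_if_m1")
  } else if (identical(m, "M1")) {
    risk <- get("mskcc_risk")
    note("mskcc_if_m1", if (is.null(risk)) NULL else risk != "poor")
  }

  list(eligible = length(violated) == 0L,
       violated = violated, indeterminate = indeterminate)
}
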