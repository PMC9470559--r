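#' Configuration of the synthetic-cohort generator
#'
#' Defaults mirror the structure of the motivating neoadjuvant VTT trial:
#' 20 evaluable patients, baseline Mayo levels distributed 4/3/9/2/2
#' across levels 0-4, a 25 percent improvement probability for
#' renal-vein-only disease and 37.5 percent for IVC disease, a Gaussian
#' model for the week-9 percent change in thrombus length, week-3 changes
#' at about half the week-9 magnitude with concordant direction, and
#' occasional missing week-9 scans and surgical dropout.
#'
#' @param n_patients Number of patients to generate.
#' @param baseline_level_probs Probabilities of baseline Mayo levels 0-4
#'   (length 5, sums to 1).
#' @param improvement_prob Per-level probability of a Mayo improvement by
#'   week 9 (length 5, indexed by baseline level 0-4), or a single
#'   probability recycled across levels.
#' @param length_change_mean,length_change_sd Mean and SD (percent) of
#'   the Gaussian week-9 length-change model; follow-up lengths are
#'   floored at zero (changes above 100 percent are truncated).
#' @param week3_fraction Week-3 change as a fraction of the week-9 change.
#' @param week3_consistency Probability that the week-3 change direction
#'   is forced to match the week-9 direction.
#' @param missing_week9_prob Probability that the week-9 scan is missing.
#' @param no_surgery_prob Probability that a patient does not proceed to
#'   surgery.
#' @param seed Integer seed; the generator is deterministic given the
#'   seed and leaves the global RNG state untouched.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20,
                          baseline_level_probs = c(4, 3, 9, 2, 2) / 20,
                          improvement_prob = c(0.25, 0.375, 0.375, 0.375,
                                               0.375),
                          length_change_mean = 20,
                          length_change_sd = 20,
                          week3_fraction = 0.5,
                          week3_consistency = 1.0,
                          missing_week9_prob = 0.15,
                          no_surgery_prob = 0.15,
                          seed = 1L) {
  if (length(n_patients) != 1L || n_patients < 1 ||
      n_patients != round(n_patients))
    stop("'n_patients' must be a positive integer", call. = FALSE)
  if (length(baseline_level_probs) != 5L || any(baseline_level_probs < 0) ||
      abs(sum(baseline_level_probs) - 1) > 1e-9)
    stop("'baseline_level_probs' must be 5 non-negative values summing to 1",
         call. = FALSE)
  if (length(improvement_prob) == 1L)
    improvement_prob <- rep(improvement_prob, 5L)
  if (length(improvement_prob) != 5L || any(improvement_prob < 0) ||
      any(improvement_prob > 1))
    stop("'improvement_prob' must be 5 probabilities (levels 0-4)",
         call. = FALSE)
  for (nm in c("week3_consistency", "missing_week9_prob", "no_surgery_prob"))
    check_prob(get(nm), nm)
  if (length_change_sd < 0) stop("'length_change_sd' must be >= 0",
                                 call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 baseline_level_probs = baseline_level_probs,
                 improvement_prob = improvement_prob,
                 length_change_mean = length_change_mean,
                 length_change_sd = length_change_sd,
                 week3_fraction = week3_fraction,
                 week3_consistency = week3_consistency,
                 missing_week9_prob = missing_week9_prob,
                 no_surgery_prob = no_surgery_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_cohort_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

empty_cohort_tables <- function() {
  list(
    patients = data.frame(
      patient_id = character(), side = character(), age = numeric(),
      weight = numeric(), sex = character(), ecog = integer(),
      urinalysis_protein = integer(), serum_creatinine = numeric(),
      creatinine_uln = numeric(), biopsy_ccrcc = logical(),
      m_stage = character(), mskcc_risk = character(),
      registered = logical(), dosed = logical(),
      central_review_excluded = logical(), stringsAsFactors = FALSE),
    assessments = data.frame(
      patient_id = character(), timepoint = character(), side = character(),
      tip_landmark = character(), tip_distance_mm = numeric(),
      rv_mm = numeric(), ivc_above_mm = numeric(), ivc_below_mm = numeric(),
      target_sum_mm = numeric(), new_lesion = logical(),
      stringsAsFactors = FALSE),
    surgery = data.frame(
      patient_id = character(), phase = character(), approach = character(),
      incision_rank = numeric(), level_of_control = integer(),
      venovenous_bypass = logical(), hypothermic_cardiac_arrest = logical(),
      pringle = logical(), stringsAsFactors = FALSE),
    ae = data.frame(
      patient_id = character(), term = character(), grade = integer(),
      related = logical(), stringsAsFactors = FALSE))
}

# bind a flat list of named row-lists into a data frame shaped like
# 'template' (typed empty table)
rows_to_df <- function(rows, template) {
  if (!length(rows)) return(template)
  cols <- lapply(names(template), function(nm) {
    v <- unlist(lapply(rows, `[[`, nm), use.names = FALSE)
    switch(class(template[[nm]]),
           integer = as.integer(v), numeric = as.numeric(v),
           logical = as.logical(v), as.character(v))
  })
  names(cols) <- names(template)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

new_cohort <- function(tables) {
  structure(tables[c("patients", "assessments", "surgery", "ae")],
            class = "vtt_cohort")
}

#' @export
print.vtt_cohort <- function(x, ...) {
  cat(sprintf("VTT trial cohort: %d patients, %d assessments, %d surgery rows, %d AE rows\n",
              nrow(x$patients), nrow(x$assessments), nrow(x$surgery),
              nrow(x$ae)))
  invisible(x)
}

# landmark/tip/length template for a baseline Mayo level
baseline_anatomy <- function(level, side) {
  if (level == 0L) {
    lm <- if (side == "left" && stats::runif(1) < 0.3)
      "rv_lateral_to_gonadal" else "rv_main"
    list(landmark = lm, tip = NA_real_,
         len = c(stats::runif(1, 20, 60), 0, 0))
  } else if (level == 1L) {
    tip <- stats::runif(1, 5, 19)
    list(landmark = "ivc", tip = tip,
         len = c(stats::runif(1, 20, 50), tip, stats::runif(1, 0, 10)))
  } else if (level == 2L) {
    tip <- stats::runif(1, 25, 90)
    list(landmark = "ivc", tip = tip,
         len = c(stats::runif(1, 25, 55), tip, stats::runif(1, 0, 20)))
  } else if (level == 3L) {
    list(landmark = "ivc_hepatic_below_diaphragm", tip = NA_real_,
         len = c(stats::runif(1, 30, 55), stats::runif(1, 90, 140),
                 stats::runif(1, 0, 20)))
  } else {
    list(landmark = "ivc_above_diaphragm", tip = NA_real_,
         len = c(stats::runif(1, 30, 55), stats::runif(1, 140, 220),
                 stats::runif(1, 0, 25)))
  }
}

# follow-up anatomy after a one-level Mayo reduction
improved_anatomy <- function(level, side, baseline) {
  if (level == 0L) {
    lm <- if (side == "right") "rv_branches"
          else if (baseline$landmark == "rv_main") "rv_lateral_to_gonadal"
          else "rv_branches"
    list(landmark = lm, tip = NA_real_)
  } else if (level == 1L) {
    list(landmark = "rv_main", tip = NA_real_)
  } else if (level == 2L) {
    list(landmark = "ivc", tip = stats::runif(1, 5, 15))
  } else if (level == 3L) {
    list(landmark = "ivc", tip = stats::runif(1, 25, 70))
  } else {
    list(landmark = "ivc_hepatic_below_diaphragm", tip = NA_real_)
  }
}

planned_control_for_level <- function(level) {
  switch(level + 1L, 1L, 2L, sample(2:3, 1L), 4L, 6L)
}

#' Generate a seeded synthetic trial cohort
#'
#' Draws baseline Mayo levels from the configured distribution, assigns
#' Mayo improvement per level, generates thrombus length trajectories
#' from the Gaussian percent-change model (responders constrained to
#' shrink), applies week-3 direction concordance, missing week-9 scans
#' and surgical dropout, and fills in surgery plans, RECIST target-lesion
#' sums, eligibility covariates and a small set of treatment-related
#' adverse events. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `vtt_cohort`: a list of data frames `patients`,
#'   `assessments`, `surgery` and `ae` (see [read_cohort()] for the
#'   column schemas).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' coh$patients$patient_id
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_cohort_rng(config$seed, {
    pts <- list(); asm <- list(); surg <- list(); aes <- list()
    # rows are accumulated as plain lists and bound once at the end so
    # that large cohorts (used for law-of-large-numbers checks) stay fast
    ae_terms <- c(hypertension = 0.5, fatigue = 0.55, diarrhoea = 0.45,
                  palmar_plantar_erythrodysesthesia = 0.25,
                  dysphonia = 0.25, hypothyroidism = 0.2)
    for (i in seq_len(config$n_patients)) {
      id <- sprintf("S%03d", i)
      side <- sample(c("left", "right"), 1L)
      level <- sample(0:4, 1L, prob = config$baseline_level_probs)
      base <- baseline_anatomy(level, side)
      responder <- stats::runif(1) < config$improvement_prob[level + 1L]

      # week-9 percent reduction in summed length; responders shrink
      pct9 <- stats::rnorm(1, config$length_change_mean,
                           config$length_change_sd)
      if (responder) pct9 <- abs(pct9)
      pct9 <- min(pct9, 100)
      pct3 <- config$week3_fraction * pct9 +
        stats::rnorm(1, 0, config$length_change_sd / 4)
      if (stats::runif(1) < config$week3_consistency &&
          sign(pct3) != sign(pct9) && pct9 != 0)
        pct3 <- -pct3
      pct3 <- min(pct3, 100)

      miss9 <- stats::runif(1) < config$missing_week9_prob
      fu <- if (responder) improved_anatomy(level, side, base)
            else base[c("landmark", "tip")]
      scale_len <- function(pct, landmark) {
        len <- pmax(base$len * (1 - pct / 100), 0)
        if (startsWith(landmark, "rv")) # regressed into the renal vein
          len <- c(sum(len), 0, 0)
        len
      }
      len3 <- scale_len(pct3, base$landmark)
      len9 <- scale_len(pct9, fu$landmark)

      tgt0 <- stats::runif(1, 60, 150)
      tgt3 <- max(tgt0 * (1 - 0.15 * pct3 / 100 + stats::rnorm(1, 0, 0.03)), 0)
      tgt9 <- max(tgt0 * (1 - 0.3 * pct9 / 100 + stats::rnorm(1, 0, 0.05)), 0)
      newles9 <- stats::runif(1) < 0.05

      # measurements are recorded to 0.1 mm, like the source imaging reads
      row <- function(tp, landmark, tip, len, tgt, newles) {
        list(patient_id = id, timepoint = tp, side = side,
             tip_landmark = landmark,
             tip_distance_mm = round(as.numeric(tip), 1),
             rv_mm = round(len[1], 1), ivc_above_mm = round(len[2], 1),
             ivc_below_mm = round(len[3], 1),
             target_sum_mm = round(tgt, 1), new_lesion = newles)
      }
      a <- list(row("baseline", base$landmark, base$tip, base$len, tgt0,
                    FALSE),
                row("week3", base$landmark, base$tip, len3, tgt3, FALSE))
      if (!miss9)
        a <- c(a, list(row("week9", fu$landmark, fu$tip, len9, tgt9,
                           newles9)))
      asm[[i]] <- a

      # surgery: planned from baseline anatomy; responders often step down
      if (stats::runif(1) >= config$no_surgery_prob) {
        ctl_p <- planned_control_for_level(level)
        app_p <- if (level == 0L && stats::runif(1) < 0.5)
          "minimally_invasive" else "open"
        inc_p <- ctl_p
        ctl_f <- ctl_p; app_f <- app_p; inc_f <- inc_p
        if (responder && stats::runif(1) < 0.6) {
          ctl_f <- max(ctl_p - 1L, 1L)
          inc_f <- max(inc_p - 1L, 1L)
          if (level == 0L && app_p == "open") app_f <- "minimally_invasive"
        }
        srow <- function(phase, app, inc, ctl)
          list(patient_id = id, phase = phase, approach = app,
               incision_rank = as.numeric(inc),
               level_of_control = as.integer(ctl),
               venovenous_bypass = FALSE,
               hypothermic_cardiac_arrest = ctl == 6L, pringle = FALSE)
        surg[[i]] <- list(srow("planned", app_p, inc_p, ctl_p),
                          srow("performed", app_f, inc_f, ctl_f))
      }

      hit <- stats::runif(length(ae_terms)) < ae_terms
      if (any(hit)) {
        grades <- sample(1:3, sum(hit), replace = TRUE,
                         prob = c(0.5, 0.35, 0.15))
        rel <- stats::runif(sum(hit)) < 0.9
        aes[[i]] <- lapply(seq_len(sum(hit)), function(k)
          list(patient_id = id, term = names(ae_terms)[hit][k],
               grade = as.integer(grades[k]), related = rel[k]))
      }

      m1 <- stats::runif(1) < 0.48
      pts[[i]] <- list(
        patient_id = id, side = side,
        age = round(stats::runif(1, 45, 80)),
        weight = round(stats::runif(1, 55, 105), 1),
        sex = sample(c("male", "female"), 1L, prob = c(0.7, 0.3)),
        ecog = as.integer(sample(0:1, 1L, prob = c(0.6, 0.4))),
        urinalysis_protein = as.integer(sample(0:1, 1L, prob = c(0.8, 0.2))),
        serum_creatinine = round(stats::runif(1, 0.7, 1.5), 2),
        creatinine_uln = 1.2,
        biopsy_ccrcc = TRUE,
        m_stage = if (m1) "M1" else "M0",
        mskcc_risk = if (m1) "intermediate" else NA_character_,
        registered = TRUE, dosed = TRUE, central_review_excluded = FALSE)
    }
    tabs <- empty_cohort_tables()
    out <- new_cohort(list(
      patients = rows_to_df(pts, tabs$patients),
      assessments = rows_to_df(unlist(asm, recursive = FALSE),
                               tabs$assessments),
      surgery = rows_to_df(unlist(surg, recursive = FALSE), tabs$surgery),
      ae = rows_to_df(unlist(aes, recursive = FALSE), tabs$ae)))
    validate_cohort(out)
    out
  })
}

#' Deterministic 20-patient reference cohort
#'
#' A hand-constructed synthetic cohort reproducing the published
#' aggregate structure of the motivating trial's evaluable population:
#' baseline Mayo levels distributed 4/3/9/2/2 over levels 0-4; seven
#' patients improved by week 9 (six with IVC involvement, one
#' renal-vein-only left-sided patient improving by the gonadal-vein
#' rule); no patient worsened; 15 of 20 with some reduction in thrombus
#' length; three patients without a week-9 scan (their week-3 scan is the
#' endpoint fallback); 17 operated patients of whom seven had less
#' extensive surgery than planned (by approach, level of control or
#' incision criteria). Individual patients are synthetic: only the
#' aggregates are meaningful. Contains no randomness.
#'
#' @return A `vtt_cohort` (see [generate_cohort()]).
#' @export
reference_cohort <- function() {
  L <- function(id, tp, side, lm, tip, rv, abv, blw, tgt, nl = FALSE)
    data.frame(patient_id = id, timepoint = tp, side = side,
               tip_landmark = lm, tip_distance_mm = tip, rv_mm = rv,
               ivc_above_mm = abv, ivc_below_mm = blw, target_sum_mm = tgt,
               new_lesion = nl, stringsAsFactors = FALSE)
  a <- rbind(
    # -- level 0 (4 patients) ------------------------------------------
    # P01: left, gonadal-rule responder; 45% length reduction; RECIST PR
    L("P01", "baseline", "left", "rv_main", NA, 40, 0, 0, 100),
    L("P01", "week3", "left", "rv_main", NA, 32, 0, 0, 98),
    L("P01", "week9", "left", "rv_lateral_to_gonadal", NA, 22, 0, 0, 65),
    # P02: left, already lateral to gonadal, stable; 10% reduction
    L("P02", "baseline", "left", "rv_lateral_to_gonadal", NA, 30, 0, 0, 88),
    L("P02", "week3", "left", "rv_lateral_to_gonadal", NA, 29, 0, 0, 88),
    L("P02", "week9", "left", "rv_lateral_to_gonadal", NA, 27, 0, 0, 84),
    # P03: right, stable; minimal (2%) reduction
    L("P03", "baseline", "right", "rv_main", NA, 50, 0, 0, 120),
    L("P03", "week3", "right", "rv_main", NA, 49.5, 0, 0, 119),
    L("P03", "week9", "right", "rv_main", NA, 49, 0, 0, 112),
    # P04: right, branches at baseline, no length change
    L("P04", "baseline", "right", "rv_branches", NA, 20, 0, 0, 70),
    L("P04", "week3", "right", "rv_branches", NA, 20, 0, 0, 70),
    L("P04", "week9", "right", "rv_branches", NA, 20, 0, 0, 69),
    # -- level 1 (3 patients) ------------------------------------------
    # P05: responder 1 -> 0, 51% reduction (largest); RECIST PR
    L("P05", "baseline", "right", "ivc", 15, 30, 15, 5, 120),
    L("P05", "week3", "right", "ivc", 15, 26, 15, 6, 115),
    L("P05", "week9", "right", "rv_main", NA, 24.5, 0, 0, 80),
    # P06: stable level 1, 12% reduction
    L("P06", "baseline", "left", "ivc", 10, 35, 10, 5, 95),
    L("P06", "week3", "left", "ivc", 10, 33, 9, 5, 95),
    L("P06", "week9", "left", "ivc", 10, 31, 8, 5, 92),
    # P07: stable level 1, 5% growth
    L("P07", "baseline", "right", "ivc", 19, 25, 19, 6, 105),
    L("P07", "week3", "right", "ivc", 19, 25.5, 19, 6.5, 106),
    L("P07", "week9", "right", "ivc", 19.5, 26, 19.5, 7, 107),
    # -- level 2 (9 patients) ------------------------------------------
    # P08: responder 2 -> 1, 35% reduction; RECIST PR
    L("P08", "baseline", "right", "ivc", 40, 40, 40, 10, 110),
    L("P08", "week3", "right", "ivc", 25, 40, 25, 10, 104),
    L("P08", "week9", "right", "ivc", 10.5, 38, 10.5, 10, 75),
    # P09: responder 2 -> 1, 28% reduction
    L("P09", "baseline", "left", "ivc", 25, 35, 25, 10, 90),
    L("P09", "week3", "left", "ivc", 20, 32, 20, 8, 89),
    L("P09", "week9", "left", "ivc", 15.4, 30, 15.4, 5, 85),
    # P10: baseline tip exactly 20 mm (level-2 boundary), responder, 40%
    L("P10", "baseline", "right", "ivc", 20, 30, 20, 10, 100),
    L("P10", "week3", "right", "ivc", 12, 28, 12, 8, 97),
    L("P10", "week9", "right", "ivc", 5, 26, 5, 5, 96),
    # P11: week-9 scan missing; week-3 fallback, stable, 8% reduction
    L("P11", "baseline", "right", "ivc", 55, 45, 55, 10, 130),
    L("P11", "week3", "right", "ivc", 50, 41.2, 50, 10, 126),
    # P12: week-9 scan missing; week-3 fallback, stable, 16% reduction
    L("P12", "baseline", "left", "ivc", 70, 40, 70, 15, 140),
    L("P12", "week3", "left", "ivc", 55, 35, 55, 15, 135),
    # P13: stable, 5% reduction
    L("P13", "baseline", "right", "ivc", 30, 30, 30, 10, 96),
    L("P13", "week3", "right", "ivc", 29, 29, 29, 10, 96),
    L("P13", "week9", "right", "ivc", 28.5, 28, 28.5, 10, 94),
    # P14: stable Mayo but 34% length reduction (VTT PR without
    # level change)
    L("P14", "baseline", "left", "ivc", 45, 35, 45, 20, 125),
    L("P14", "week3", "left", "ivc", 38, 30, 38, 15, 121),
    L("P14", "week9", "left", "ivc", 31, 25, 31, 10, 118),
    # P15: 10% growth; RECIST PD by target-lesion growth
    L("P15", "baseline", "right", "ivc", 60, 40, 60, 20, 90),
    L("P15", "week3", "right", "ivc", 63, 42, 63, 21, 91),
    L("P15", "week9", "right", "ivc", 66, 44, 66, 22, 110),
    # P16: 20% growth; RECIST PD by new lesion
    L("P16", "baseline", "left", "ivc", 80, 45, 80, 15, 100),
    L("P16", "week3", "left", "ivc", 88, 49.5, 88, 16.5, 100),
    L("P16", "week9", "left", "ivc", 96, 54, 96, 18, 102, nl = TRUE),
    # -- level 3 (2 patients) ------------------------------------------
    # P17: responder 3 -> 2, 33% reduction
    L("P17", "baseline", "right", "ivc_hepatic_below_diaphragm", NA,
      40, 100, 20, 150),
    L("P17", "week3", "right", "ivc_hepatic_below_diaphragm", NA,
      36, 85, 15, 147),
    L("P17", "week9", "right", "ivc", 50, 47.2, 50, 10, 140),
    # P18: stable level 3, 9% reduction
    L("P18", "baseline", "left", "ivc_hepatic_below_diaphragm", NA,
      35, 110, 15, 135),
    L("P18", "week3", "left", "ivc_hepatic_below_diaphragm", NA,
      33, 105, 14, 134),
    L("P18", "week9", "left", "ivc_hepatic_below_diaphragm", NA,
      32, 100, 13.6, 130),
    # -- level 4 (2 patients) ------------------------------------------
    # P19: responder 4 -> 3, 31% reduction
    L("P19", "baseline", "right", "ivc_above_diaphragm", NA, 40, 180, 20,
      160),
    L("P19", "week3", "right", "ivc_above_diaphragm", NA, 36, 152, 16, 158),
    L("P19", "week9", "right", "ivc_hepatic_below_diaphragm", NA,
      40.6, 110, 15, 150),
    # P20: week-9 scan missing; week-3 fallback shows 15% growth
    L("P20", "baseline", "left", "ivc_above_diaphragm", NA, 45, 200, 25,
      170),
    L("P20", "week3", "left", "ivc_above_diaphragm", NA, 50, 232.5, 28, 172))

  S <- function(id, app_p, ctl_p, inc_p, app_f, ctl_f, inc_f,
                vv = c(FALSE, FALSE), hca = c(FALSE, FALSE))
    data.frame(patient_id = id, phase = c("planned", "performed"),
               approach = c(app_p, app_f), incision_rank = c(inc_p, inc_f),
               level_of_control = as.integer(c(ctl_p, ctl_f)),
               venovenous_bypass = vv, hypothermic_cardiac_arrest = hca,
               pringle = FALSE, stringsAsFactors = FALSE)
  # 17 operated patients (P07, P16, P20 not operated); 7 less extensive
  s <- rbind(
    S("P01", "open", 1, 2, "minimally_invasive", 1, 1), # approach reduced
    S("P02", "open", 2, 2, "open", 1, 2),               # control reduced
    S("P03", "minimally_invasive", 1, 1, "minimally_invasive", 1, 1),
    S("P04", "minimally_invasive", 1, 1, "minimally_invasive", 1, 1),
    S("P05", "open", 2, 2, "open", 1, 1),               # control reduced
    S("P06", "open", 2, 2, "open", 2, 2),
    S("P08", "open", 3, 3, "open", 2, 2),               # control reduced
    S("P09", "open", 2, 2, "open", 2, 2),
    S("P10", "open", 3, 2, "open", 3, 2),
    S("P11", "open", 3, 3, "open", 3, 3),
    S("P12", "open", 3, 3, "open", 3, 3),
    S("P13", "open", 2, 2, "open", 2, 2),
    S("P14", "open", 2, 3, "open", 2, 2),               # incision reduced
    S("P15", "open", 3, 3, "open", 3, 3),
    S("P17", "open", 5, 4, "open", 3, 3),               # control reduced
    S("P18", "open", 5, 4, "open", 5, 4),
    S("P19", "open", 6, 5, "open", 4, 4,                # control reduced
      hca = c(TRUE, FALSE)))

  ae <- data.frame(
    patient_id = c("P01", "P01", "P02", "P03", "P05", "P06", "P08", "P08",
                   "P10", "P13", "P15", "P19"),
    term = c("hypertension", "hypertension", "hypertension", "fatigue",
             "diarrhoea", "hypertension", "fatigue", "fatigue",
             "diarrhoea", "dysphonia", "hypertension", "fatigue"),
    grade = as.integer(c(2, 3, 1, 1, 2, 2, 2, 2, 1, 1, 3, 1)),
    related = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                TRUE, FALSE),
    stringsAsFactors = FALSE)

  ids <- sprintf("P%02d", 1:20)
  sides <- vapply(ids, function(i) a$side[a$patient_id == i][1], "")
  m1 <- ids %in% c("P02", "P05", "P07", "P09", "P11", "P13", "P15", "P17",
                   "P19")
  p <- data.frame(
    patient_id = ids, side = unname(sides),
    age = c(69, 55, 72, 61, 49, 66, 58, 74, 63, 70, 52, 67, 59, 71, 64, 56,
            68, 62, 75, 78),
    weight = c(82, 74.5, 90, 68, 77, 85, 71, 94, 66, 88, 79, 72, 83, 69, 91,
               76, 87, 70, 80, 73),
    sex = c("male", "female", "male", "male", "female", "male", "male",
            "male", "female", "male", "male", "female", "male", "male",
            "female", "male", "male", "female", "male", "male"),
    ecog = as.integer(c(0, 0, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 0, 1, 0, 1, 0,
                        0, 1, 0)),
    urinalysis_protein = as.integer(c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0,
                                      0, 0, 0, 1, 0, 0, 0)),
    serum_creatinine = c(1.0, 0.8, 1.2, 0.9, 0.7, 1.1, 1.0, 1.3, 0.8, 1.0,
                         0.9, 1.1, 1.2, 1.0, 0.9, 1.4, 1.0, 0.8, 1.1, 1.2),
    creatinine_uln = 1.2,
    biopsy_ccrcc = TRUE,
    m_stage = ifelse(m1, "M1", "M0"),
    mskcc_risk = ifelse(m1, "intermediate", NA_character_),
    registered = TRUE, dosed = TRUE, central_review_excluded = FALSE,
    stringsAsFactors = FALSE)

  out <- new_cohort(list(patients = p, assessments = a, surgery = s,
                         ae = ae))
  validate_cohort(out)
  out
}

#' Validate a cohort against the endpoint-module invariants
#'
#' Checks enumerations, required columns, non-negative lengths, the
#' left-only gonadal landmark and the tip-distance requirement for IVC
#' landmarks by running every assessment row through [vtt_assessment()]
#' and [vtt_lengths()], and checks surgery and adverse-event rows.
#' Errors name the offending table and row.
#'
#' @param cohort A `vtt_cohort`.
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "vtt_cohort") || is.list(cohort))
  a <- cohort$assessments
  errs <- character(0)
  flag <- function(bad, msg, tab = "assessments", ids = a$patient_id) {
    bad <- which(bad)
    if (length(bad))
      errs <<- c(errs, sprintf("%s row %d (%s): %s", tab, bad,
                               ids[bad], msg))
  }
  if (nrow(a)) {
    flag(!a$timepoint %in% TIMEPOINTS, "unknown timepoint")
    flag(!a$side %in% c("left", "right"), "unknown side")
    flag(!a$tip_landmark %in% TIP_LANDMARKS, "unknown tip landmark")
    flag(a$tip_landmark == "rv_lateral_to_gonadal" & a$side != "left",
         "'rv_lateral_to_gonadal' is defined only for left-sided thrombi")
    flag(a$tip_landmark == "ivc" & is.na(a$tip_distance_mm),
         "an 'ivc' landmark requires 'tip_distance_mm'")
    flag(!is.na(a$tip_distance_mm) & a$tip_distance_mm < 0,
         "'tip_distance_mm' must be >= 0")
    for (col in c("rv_mm", "ivc_above_mm", "ivc_below_mm"))
      flag(!is.finite(a[[col]]) | a[[col]] < 0,
           sprintf("'%s' must be finite and >= 0", col))
    flag(startsWith(a$tip_landmark, "rv") &
           (a$ivc_above_mm > 0 | a$ivc_below_mm > 0),
         "renal-vein-only assessment has non-zero IVC lengths")
  }
  s <- cohort$surgery
  if (nrow(s)) {
    flag(!s$phase %in% c("planned", "performed"), "unknown phase",
         "surgery", s$patient_id)
    flag(!s$approach %in% SURGICAL_APPROACHES, "unknown approach",
         "surgery", s$patient_id)
    flag(!s$level_of_control %in% 1:6,
         "'level_of_control' must be an integer 1-6", "surgery",
         s$patient_id)
    flag(!is.finite(s$incision_rank) | s$incision_rank < 0,
         "'incision_rank' must be a non-negative ordinal", "surgery",
         s$patient_id)
  }
  if (nrow(cohort$ae) && any(!cohort$ae$grade %in% 1:5))
    errs <- c(errs, sprintf("ae rows %s: grade outside 1-5",
                            paste(which(!cohort$ae$grade %in% 1:5),
                                  collapse = ", ")))
  orphan <- setdiff(unique(a$patient_id), cohort$patients$patient_id)
  if (length(orphan))
    errs <- c(errs, sprintf("assessments reference unknown patients: %s",
                            paste(orphan, collapse = ", ")))
  if (length(errs))
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(cohort)
}

cohort_col_classes <- function() {
  lapply(empty_cohort_tables(), function(d) vapply(d, class, ""))
}

#' Write a cohort to CSV files / read it back
#'
#' `write_cohort()` serialises the four cohort tables to
#' `patients.csv`, `assessments.csv`, `surgery.csv` and `ae.csv` inside
#' `dir`. `read_cohort()` reads them back with fixed column classes and
#' validates enumerations row by row, so that
#' `read_cohort(write_cohort(x))` is the identity.
#'
#' @param cohort A `vtt_cohort`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   `vtt_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vtt_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort))
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  classes <- cohort_col_classes()
  tabs <- list()
  for (nm in names(classes)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path))
      stop(sprintf("missing cohort file: %s", path), call. = FALSE)
    cls <- classes[[nm]]
    d <- tryCatch(
      utils::read.csv(path, colClasses = cls, stringsAsFactors = FALSE),
      error = function(e)
        stop(sprintf("malformed %s.csv: %s", nm, conditionMessage(e)),
             call. = FALSE))
    if (!identical(names(d), names(cls)))
      stop(sprintf("%s.csv: expected columns %s", nm,
                   paste(names(cls), collapse = ", ")), call. = FALSE)
    tabs[[nm]] <- d
  }
  if (nrow(tabs$patients) == 0L)
    warning("cohort is empty", call. = FALSE)
  out <- new_cohort(tabs)
  validate_cohort(out)
  out
}
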