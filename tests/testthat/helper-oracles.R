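# Independent brute-force oracles. These deliberately re-derive the
# quantities by exhaustive enumeration over the two-stage outcome space
# (all (x1, x2) pairs) or by direct re-implementation of the endpoint
# rules, and are kept free of the package's own computational shortcuts.

# P(X1 > r1 and X1 + X2 > r) by full enumeration of all (x1, x2) pairs
bf_reject <- function(r1, n1, r, n, p) {
  n2 <- n - n1
  x1 <- 0:n1; x2 <- 0:n2
  prob <- outer(dbinom(x1, n1, p), dbinom(x2, n2, p))
  keep <- outer(x1, x2, function(a, b) a > r1 & a + b > r)
  sum(prob[keep])
}

# P(reach stage 2 and X1 + X2 >= x) by full enumeration
bf_tail <- function(x, r1, n1, n2, p) {
  x1 <- 0:n1; x2 <- 0:n2
  prob <- outer(dbinom(x1, n1, p), dbinom(x2, n2, p))
  keep <- outer(x1, x2, function(a, b) a > r1 & a + b >= x)
  sum(prob[keep])
}

# full outcome distribution of the two-stage rule at response rate p:
# one row per terminal outcome (stage-1 stop at x1, or stage-2 total x)
outcome_distribution <- function(design, p) {
  r1 <- design$r1; n1 <- design$n1; n2 <- design$n2
  rows <- list()
  for (x1 in 0:r1)
    rows[[length(rows) + 1]] <- data.frame(
      x = x1, stopped = TRUE, prob = dbinom(x1, n1, p))
  for (x1 in (r1 + 1):n1) for (x2 in 0:n2)
    rows[[length(rows) + 1]] <- data.frame(
      x = x1 + x2, stopped = FALSE,
      prob = dbinom(x1, n1, p) * dbinom(x2, n2, p))
  d <- do.call(rbind, rows)
  stopifnot(abs(sum(d$prob) - 1) < 1e-12)
  d
}

# independent vectorised re-count of Mayo improvements in a cohort,
# re-stating the endpoint rules directly on the assessment table
oracle_count_improved <- function(cohort) {
  a <- cohort$assessments
  level_of <- function(lm, tip) {
    ifelse(lm %in% c("rv_branches", "rv_lateral_to_gonadal", "rv_main"), 0,
    ifelse(lm == "ivc", ifelse(tip < 20, 1, 2),
    ifelse(lm == "ivc_hepatic_below_diaphragm", 3, 4)))
  }
  sub_rank <- function(lm) match(lm, c("rv_branches", "rv_lateral_to_gonadal",
                                       "rv_main"))
  n_improved <- 0L
  for (id in unique(a$patient_id)) {
    base <- a[a$patient_id == id & a$timepoint == "baseline", ]
    fu <- a[a$patient_id == id & a$timepoint == "week9", ]
    if (nrow(fu) == 0) fu <- a[a$patient_id == id & a$timepoint == "week3", ]
    if (nrow(base) == 0 || nrow(fu) == 0) next
    l0 <- level_of(base$tip_landmark, base$tip_distance_mm)
    l1 <- level_of(fu$tip_landmark, fu$tip_distance_mm)
    improved <- if (l0 >= 1) l1 < l0
      else l1 == 0 && sub_rank(fu$tip_landmark) < sub_rank(base$tip_landmark)
    if (isTRUE(improved)) n_improved <- n_improved + 1L
  }
  n_improved
}

# sort-based median, independent of stats::median
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

trial_design_2020 <- function() two_stage_design(r1 = 0, n1 = 13, r = 2,
                                                 n = 20)
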