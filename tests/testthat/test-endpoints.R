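test_that("Mayo classification follows the anatomical definitions", {
  expect_equal(classify_mayo(vtt_assessment("right", "rv_main")), 0L)
  expect_equal(classify_mayo(vtt_assessment("left", "rv_lateral_to_gonadal")),
               0L)
  expect_equal(classify_mayo(vtt_assessment("right", "ivc", 15)), 1L)
  expect_equal(classify_mayo(vtt_assessment("right", "ivc", 19.9)), 1L)
  # the 2 cm boundary is level 2: level 1 is strictly below 2 cm
  expect_equal(classify_mayo(vtt_assessment("right", "ivc", 20)), 2L)
  expect_equal(classify_mayo(vtt_assessment("right", "ivc", 85)), 2L)
  expect_equal(
    classify_mayo(vtt_assessment("left", "ivc_hepatic_below_diaphragm")), 3L)
  expect_equal(classify_mayo(vtt_assessment("left", "ivc_above_diaphragm")),
               4L)
  expect_error(vtt_assessment("right", "ivc"), "tip_distance_mm")
  expect_error(vtt_assessment("right", "rv_lateral_to_gonadal"),
               "left-sided")
  expect_error(vtt_assessment("right", "ivc", -3), ">= 0")
})

test_that("Mayo level is monotone in cranial extent of the tip", {
  craniad <- list(
    vtt_assessment("left", "rv_branches"),
    vtt_assessment("left", "rv_lateral_to_gonadal"),
    vtt_assessment("left", "rv_main"),
    vtt_assessment("left", "ivc", 5),
    vtt_assessment("left", "ivc", 19),
    vtt_assessment("left", "ivc", 20),
    vtt_assessment("left", "ivc", 90),
    vtt_assessment("left", "ivc_hepatic_below_diaphragm"),
    vtt_assessment("left", "ivc_above_diaphragm"))
  levels <- vapply(craniad, classify_mayo, 0L)
  expect_true(all(diff(levels) >= 0))
  # random increasing tip distances never decrease the level
  set.seed(11)
  tips <- sort(runif(50, 0, 120))
  lv <- vapply(tips, function(t)
    classify_mayo(vtt_assessment("right", "ivc", t)), 0L)
  expect_true(all(diff(lv) >= 0))
})

test_that("improvement calls implement the level- and gonadal-vein rules", {
  imp <- function(b, f) mayo_improvement(b, f)
  # reduction across IVC levels
  expect_equal(imp(vtt_assessment("right", "ivc", 40),
                   vtt_assessment("right", "ivc", 10, "week9")), "improved")
  expect_equal(imp(vtt_assessment("right", "ivc", 10),
                   vtt_assessment("right", "ivc", 45, "week9")), "worsened")
  expect_equal(imp(vtt_assessment("left", "ivc_above_diaphragm"),
                   vtt_assessment("left", "ivc_hepatic_below_diaphragm",
                                  timepoint = "week9")), "improved")
  # level-0 sub-level moves
  expect_equal(imp(vtt_assessment("left", "rv_main"),
                   vtt_assessment("left", "rv_lateral_to_gonadal",
                                  timepoint = "week9")), "improved")
  expect_equal(imp(vtt_assessment("left", "rv_lateral_to_gonadal"),
                   vtt_assessment("left", "rv_branches",
                                  timepoint = "week9")), "improved")
  expect_equal(imp(vtt_assessment("right", "rv_main"),
                   vtt_assessment("right", "rv_branches",
                                  timepoint = "week9")), "improved")
  # worsening from level 0 means extension into the IVC ...
  expect_equal(imp(vtt_assessment("right", "rv_main"),
                   vtt_assessment("right", "ivc", 8, "week9")), "worsened")
  # ... while craniad movement within the renal vein is reported stable
  expect_equal(imp(vtt_assessment("right", "rv_branches"),
                   vtt_assessment("right", "rv_main", timepoint = "week9")),
               "stable")
  expect_equal(imp(vtt_assessment("left", "ivc", 30),
                   vtt_assessment("left", "ivc", 30, "week9")), "stable")
  expect_error(imp(vtt_assessment("left", "rv_main"),
                   vtt_assessment("right", "rv_main", timepoint = "week9")),
               "different sides")
})

test_that("improvement is antisymmetric for IVC-level disease", {
  set.seed(23)
  mk <- function() {
    kind <- sample(3, 1)
    if (kind == 1) vtt_assessment("right", "ivc", runif(1, 0, 100))
    else if (kind == 2) vtt_assessment("right",
                                       "ivc_hepatic_below_diaphragm")
    else vtt_assessment("right", "ivc_above_diaphragm")
  }
  flip <- c(improved = "worsened", stable = "stable",
            worsened = "improved")
  for (i in 1:50) {
    a <- mk(); b <- mk()
    expect_equal(mayo_improvement(b, a),
                 unname(flip[mayo_improvement(a, b)]))
  }
})

test_that("thrombus length sums and percent change follow the formula", {
  expect_equal(vtt_sum(vtt_lengths(10)), 10)
  expect_equal(vtt_sum(vtt_lengths(10, 25, 5)), 40)
  expect_error(vtt_lengths(-1, 0, 0), ">= 0")
  expect_equal(vtt_percent_change(vtt_lengths(20, 15, 5),
                                  vtt_lengths(10, 8, 2)), 50)
  expect_equal(vtt_percent_change(vtt_lengths(30, 5, 5),
                                  vtt_lengths(30, 5, 5)), 0)
  expect_equal(vtt_percent_change(vtt_lengths(25), vtt_lengths(0)), 100)
  expect_equal(vtt_percent_change(vtt_lengths(40), vtt_lengths(48)), -20)
  expect_error(vtt_percent_change(vtt_lengths(0, 0, 0), vtt_lengths(5)),
               "undefined")
})

test_that("percent change is invariant to rescaling all lengths", {
  set.seed(5)
  for (i in 1:25) {
    b <- runif(3, 0.5, 80); f <- runif(3, 0, 80); c0 <- runif(1, 0.01, 50)
    expect_equal(
      vtt_percent_change(vtt_lengths(b[1], b[2], b[3]),
                         vtt_lengths(f[1], f[2], f[3])),
      vtt_percent_change(vtt_lengths(c0 * b[1], c0 * b[2], c0 * b[3]),
                         vtt_lengths(c0 * f[1], c0 * f[2], c0 * f[3])),
      tolerance = 1e-9)
  }
})

test_that("thrombus response requires strictly more than 30% shrinkage", {
  expect_equal(vtt_response(51), "VTT_PR")
  expect_equal(vtt_response(30), "no_VTT_PR")
  expect_equal(vtt_response(30.0001), "VTT_PR")
  expect_equal(vtt_response(-20), "no_VTT_PR")
})

test_that("RECIST classification applies the v1.1 thresholds", {
  expect_equal(recist_classify(100, 70), "PR")
  expect_equal(recist_classify(100, 70.1), "SD")
  expect_equal(recist_classify(100, 0), "CR")
  expect_equal(recist_classify(100, 61, nadir_sum = 50), "PD")
  expect_equal(recist_classify(100, 95, nadir_sum = 95), "SD")
  # 20% growth from nadir but under 5 mm absolute is not progression
  expect_equal(recist_classify(100, 14, nadir_sum = 10), "PR")
  expect_equal(recist_classify(10, 14, nadir_sum = 10), "SD")
  # growth-based progression outranks response from baseline
  expect_equal(recist_classify(100, 65, nadir_sum = 50), "PD")
  # a new lesion is always progression, even with complete target response
  set.seed(9)
  for (i in 1:20) {
    b <- runif(1, 10, 150); cur <- runif(1, 0, 150)
    expect_equal(recist_classify(b, cur, new_lesion = TRUE), "PD")
  }
  expect_error(recist_classify(-1, 10), ">= 0")
})

test_that("surgical extent comparison applies the three criteria", {
  plan <- function(app = "open", ctl = 3, inc = 3)
    surgical_plan(app, ctl, inc)
  # supradiaphragmatic control reduced to infradiaphragmatic
  expect_equal(surgical_change(plan(ctl = 6), plan(ctl = 3))$change,
               "less_extensive")
  # infrahepatic clamping reduced to milking into the renal vein
  expect_equal(surgical_change(plan(ctl = 2), plan(ctl = 1))$change,
               "less_extensive")
  expect_equal(surgical_change(plan("open"), plan("minimally_invasive"))$change,
               "less_extensive")
  expect_equal(surgical_change(plan(inc = 3), plan(inc = 2))$change,
               "less_extensive")
  expect_equal(surgical_change(plan("minimally_invasive"), plan("open"))$change,
               "more_extensive")
  expect_equal(surgical_change(plan(ctl = 2), plan(ctl = 4))$change,
               "more_extensive")
  # any favourable criterion dominates an unfavourable one
  res <- surgical_change(plan(ctl = 4, inc = 2), plan(ctl = 2, inc = 3))
  expect_equal(res$change, "less_extensive")
  expect_true(res$control_reduced)
  expect_true(res$incision_increased)
  # identity is unchanged for arbitrary valid records
  for (ctl in 1:6) for (app in c("open", "minimally_invasive")) {
    p <- plan(app, ctl, ctl)
    expect_equal(surgical_change(p, p)$change, "unchanged")
  }
  expect_error(surgical_plan("open", 7), "1-6")
})

test_that("Cockcroft-Gault clearance follows the formula", {
  expect_equal(cockcroft_gault(70, 80, "male", 1.0), 5600 / 72,
               tolerance = 1e-12)
  expect_equal(round(cockcroft_gault(70, 80, "male", 1.0), 2), 77.78)
  expect_equal(cockcroft_gault(60, 70, "female", 1.1) /
                 cockcroft_gault(60, 70, "male", 1.1), 0.85)
  expect_equal(cockcroft_gault(50, 90, "male", 2.0),
               cockcroft_gault(50, 90, "male", 1.0) / 2)
  expect_error(cockcroft_gault(-5, 80, "male", 1), "positive")
  expect_error(cockcroft_gault(50, 80, "male", 0), "positive")
})

test_that("eligibility screening applies the protocol criteria", {
  base <- list(age = 65, ecog = 0, urinalysis_protein = 0,
               serum_creatinine = 1.0, creatinine_uln = 1.2, weight = 80,
               sex = "male", biopsy_ccrcc = TRUE, m_stage = "M0")
  ok <- eligibility_check(base)
  expect_true(ok$eligible)
  expect_length(ok$violated, 0)

  poor <- eligibility_check(modifyList(base, list(m_stage = "M1",
                                                  mskcc_risk = "poor")))
  expect_false(poor$eligible)
  expect_true("mskcc_if_m1" %in% poor$violated)
  interm <- eligibility_check(modifyList(base, list(
    m_stage = "M1", mskcc_risk = "intermediate")))
  expect_true(interm$eligible)

  # both renal criteria failing: creatinine 2x ULN and clearance < 30
  renal <- eligibility_check(modifyList(base, list(
    age = 85, weight = 45, serum_creatinine = 2.4)))
  expect_false(renal$eligible)
  expect_true("renal_function" %in% renal$violated)
  # one passing renal route suffices
  one_route <- eligibility_check(modifyList(base, list(
    serum_creatinine = 1.9))) # > 1.5x ULN but clearance ample
  expect_true(one_route$eligible)

  ecog <- eligibility_check(modifyList(base, list(ecog = 2)))
  expect_true("ecog_below_2" %in% ecog$violated)
  prot <- eligibility_check(modifyList(base, list(
    urinalysis_protein = 2, urine_protein_g24 = 3,
    protein_creatinine_ratio = 250)))
  expect_true("proteinuria" %in% prot$violated)
  prot_ok <- eligibility_check(modifyList(base, list(
    urinalysis_protein = 2, protein_creatinine_ratio = 150)))
  expect_true(prot_ok$eligible)

  # missing fields are indeterminate, not failures
  sparse <- eligibility_check(list(age = 70))
  expect_true(sparse$eligible)
  expect_true(all(c("ecog_below_2", "proteinuria", "renal_function",
                    "biopsy_ccrcc", "mskcc_if_m1") %in%
                    sparse$indeterminate))
})
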