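test_that("outcome validation rejects impossible trial results", {
  d <- trial_design_2020()
  # zero responses cannot reach stage 2
  expect_error(trial_outcome(0, d, stopped_stage1 = FALSE), "stage 1")
  # a stage-1 stop cannot exceed the futility boundary
  expect_error(trial_outcome(3, d, stopped_stage1 = TRUE), "inconsistent")
  expect_error(trial_outcome(21, d), "exceed")
  d2 <- two_stage_design(2, 10, 5, 20)
  # totals in 1..r1 are unreachable for a trial that continued
  expect_error(trial_outcome(1, d2, stopped_stage1 = FALSE), "inconsistent")
})

test_that("the p-value function matches exhaustive outcome enumeration", {
  d <- trial_design_2020()
  for (x in c(1, 2, 3, 7, 12, 20)) {
    for (p in c(0.05, 0.2, 0.5, 0.8)) {
      expect_equal(pvalue_function(x, d, p),
                   bf_tail(x, d$r1, d$n1, d$n2, p), tolerance = 1e-12)
    }
  }
  d2 <- two_stage_design(2, 9, 6, 22)
  for (x in c(3, 6, 10, 22)) {
    expect_equal(pvalue_function(x, d2, 0.3),
                 bf_tail(x, d2$r1, d2$n1, d2$n2, 0.3), tolerance = 1e-12)
  }
})

test_that("p-value degenerate cases follow the stage-wise ordering", {
  d <- trial_design_2020()
  # stopped with zero responses: P(X1 >= 0) = 1 at every p
  for (p in c(0, 0.3, 1))
    expect_equal(pvalue_function(trial_outcome(0, d, TRUE), d, p), 1)
  # no successes are possible under p0 = 0
  expect_equal(design_pvalue(7, d, 0), 0)
  # Q is non-decreasing in p with Q(0) = 0, Q(1) = 1 for x >= 1
  vals <- vapply(seq(0, 1, 0.01), function(p) pvalue_function(5, d, p), 0)
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[1], 0)
  expect_equal(vals[length(vals)], 1)
})

test_that("inference at 7/20 under the trial design reproduces the published values", {
  d <- trial_design_2020()
  inf <- design_inference(7, d, p0 = 0.05, conf_level = 0.80)
  expect_equal(signif(inf$p_value, 4), 3.395e-5)
  expect_equal(round_half_up(100 * inf$estimate, 1), 32.8)
  expect_equal(round_half_up(100 * inf$ci_lower, 1), 20.7)
  expect_equal(round_half_up(100 * inf$ci_upper, 1), 46.7)
})

test_that("the median-unbiased estimate is monotone in the response count", {
  d <- trial_design_2020()
  est <- vapply(1:20, function(x) median_unbiased_estimate(x, d), 0)
  expect_true(all(diff(est) > 0))
  expect_equal(median_unbiased_estimate(0, d), 0)
  # Q at the estimate really is one half
  for (x in c(1, 7, 15))
    expect_equal(pvalue_function(x, d, median_unbiased_estimate(x, d)),
                 0.5, tolerance = 1e-6)
})

test_that("confidence intervals bracket the estimate and nest by level", {
  d <- trial_design_2020()
  for (x in c(1, 4, 7, 13, 20)) {
    est <- median_unbiased_estimate(x, d)
    ci80 <- confidence_interval(x, d, 0.80)
    expect_lte(ci80[["lower"]], est)
    expect_gte(ci80[["upper"]], est)
    ci50 <- confidence_interval(x, d, 0.50)
    ci95 <- confidence_interval(x, d, 0.95)
    expect_gte(ci50[["lower"]], ci80[["lower"]])
    expect_lte(ci50[["upper"]], ci80[["upper"]])
    expect_lte(ci95[["lower"]], ci80[["lower"]])
    expect_gte(ci95[["upper"]], ci80[["upper"]])
  }
  # degenerate tail at zero responses
  expect_equal(confidence_interval(0, d, 0.80),
               c(lower = 0, upper = 1))
})

test_that("the UMVUE is exactly unbiased over the outcome space", {
  d <- trial_design_2020()
  for (p in c(0.05, 0.25, 0.5)) {
    dist <- outcome_distribution(d, p)
    est <- vapply(seq_len(nrow(dist)), function(i) {
      umvue(trial_outcome(dist$x[i], d, dist$stopped[i]), d)
    }, 0)
    expect_equal(sum(est * dist$prob), p, tolerance = 1e-10)
  }
  # single-term closed forms
  expect_equal(umvue(20, d), 1)
  # stage-1 stop returns the stage-1 MLE
  expect_equal(umvue(trial_outcome(0, d, TRUE), d), 0)
  d2 <- two_stage_design(2, 8, 5, 16)
  expect_equal(umvue(trial_outcome(1, d2, TRUE), d2), 1 / 8)
  # x = r1 + 1 with a single admissible stage-1 term
  d3 <- two_stage_design(1, 5, 3, 8)
  x <- 2 # j is forced to r1 + 1 = 2 with x - j = 0
  expect_equal(umvue(x, d3),
               choose(4, 1) * choose(3, 0) /
                 (choose(5, 2) * choose(3, 0)), tolerance = 1e-12)
})

test_that("the null p-value is stochastically super-uniform", {
  d <- trial_design_2020()
  p0 <- 0.05
  dist <- outcome_distribution(d, p0)
  pv <- vapply(seq_len(nrow(dist)), function(i)
    design_pvalue(trial_outcome(dist$x[i], d, dist$stopped[i]), d, p0), 0)
  for (t in seq(0, 1, by = 0.01)) {
    expect_lte(sum(dist$prob[pv <= t]), t + 1e-12)
  }
})
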