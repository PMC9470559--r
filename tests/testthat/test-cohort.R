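test_that("config validation catches malformed generator settings", {
  expect_error(cohort_config(n_patients = 0), "positive")
  expect_error(cohort_config(baseline_level_probs = c(0.5, 0.5)),
               "summing to 1")
  expect_error(cohort_config(baseline_level_probs = c(0.5, 0.2, 0.2, 0.2,
                                                      0.1)), "summing to 1")
  expect_error(cohort_config(improvement_prob = c(0.2, 1.3, 0, 0, 0)),
               "probabilities")
  expect_error(cohort_config(missing_week9_prob = -0.1), "probability")
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  set.seed(999)
  before <- .Random.seed
  a <- generate_cohort(cohort_config(seed = 42))
  expect_identical(.Random.seed, before)
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(a, c))
})

test_that("generated cohorts satisfy every endpoint-module invariant", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(n_patients = 40, seed = seed))
    expect_silent(validate_cohort(coh))
    expect_equal(nrow(coh$patients), 40)
    # surgery rows come in planned/performed pairs
    expect_true(all(table(coh$surgery$patient_id) == 2))
  }
})

test_that("zero improvement probability yields zero improved patients", {
  coh <- generate_cohort(cohort_config(n_patients = 200,
                                       improvement_prob = 0, seed = 3))
  expect_equal(oracle_count_improved(coh), 0)
})

test_that("improvement frequency converges to the configured probability", {
  n <- 20000
  coh <- generate_cohort(cohort_config(
    n_patients = n, improvement_prob = 0.35, missing_week9_prob = 0,
    seed = 2024))
  frac <- oracle_count_improved(coh) / n
  se <- sqrt(0.35 * 0.65 / n)
  expect_lt(abs(frac - 0.35), 3 * se)
})

test_that("cohort CSV round-trip is the identity", {
  for (coh in list(reference_cohort(),
                   generate_cohort(cohort_config(seed = 17)))) {
    dir <- withr::local_tempdir()
    write_cohort(coh, dir)
    expect_identical(read_cohort(dir), coh)
  }
})

test_that("malformed cohort files are rejected with located errors", {
  dir <- withr::local_tempdir()
  write_cohort(reference_cohort(), dir)
  # unknown enum value is rejected and the offending row named
  a <- read.csv(file.path(dir, "assessments.csv"))
  a$tip_landmark[5] <- "portal_vein"
  write.csv(a, file.path(dir, "assessments.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "row 5.*unknown tip landmark")
  # missing file
  file.remove(file.path(dir, "assessments.csv"))
  expect_error(read_cohort(dir), "missing cohort file")
})

test_that("an empty cohort reads back with a warning", {
  dir <- withr::local_tempdir()
  write_cohort(reference_cohort(), dir)
  for (f in c("patients", "assessments", "surgery", "ae")) {
    d <- read.csv(file.path(dir, paste0(f, ".csv")))
    write.csv(d[0, , drop = FALSE], file.path(dir, paste0(f, ".csv")),
              row.names = FALSE)
  }
  expect_warning(coh <- read_cohort(dir), "empty")
  expect_equal(nrow(coh$patients), 0)
})

test_that("the reference cohort reproduces the published aggregates", {
  coh <- reference_cohort()
  base <- coh$assessments[coh$assessments$timepoint == "baseline", ]
  level <- vapply(seq_len(nrow(base)), function(i)
    classify_mayo(vtt_assessment(base$side[i], base$tip_landmark[i],
                                 base$tip_distance_mm[i])), 0L)
  expect_equal(as.integer(table(factor(level, levels = 0:4))),
               c(4L, 3L, 9L, 2L, 2L))
  expect_equal(oracle_count_improved(coh), 7)
  expect_equal(nrow(coh$patients), 20)
  # exactly three patients lack a week-9 scan
  wk9 <- unique(coh$assessments$patient_id[
    coh$assessments$timepoint == "week9"])
  expect_length(setdiff(coh$patients$patient_id, wk9), 3)
})

test_that("the committed fixture files are byte-identical to the generator", {
  committed <- system.file("extdata", "reference_cohort",
                           package = "vttrial")
  expect_true(dir.exists(committed))
  dir <- withr::local_tempdir()
  write_cohort(reference_cohort(), dir)
  for (f in c("patients.csv", "assessments.csv", "surgery.csv", "ae.csv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(committed, f)), label = f)
  }
})
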