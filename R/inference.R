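#' Observed outcome of a two-stage trial
#'
#' @param total_responses Total number of responders observed (`x`).
#' @param stopped_stage1 `TRUE` if accrual halted at the stage-1 futility
#'   look. When `TRUE`, `total_responses` is the stage-1 count `x1` and
#'   must satisfy `x1 <= r1`.
#' @param design The [two_stage_design()] the trial followed; used to
#'   validate consistency.
#' @return An object of class `trial_outcome`.
#' @export
trial_outcome <- function(total_responses, design, stopped_stage1 = FALSE) {
  design <- as_two_stage_design(design)
  x <- total_responses
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < 0)
    stop("'total_responses' must be a single non-negative integer",
         call. = FALSE)
  x <- as.integer(x)
  if (isTRUE(stopped_stage1)) {
    if (x > design$r1)
      stop(sprintf(
        "inconsistent outcome: trial stopped at stage 1 but x1 = %d > r1 = %d",
        x, design$r1), call. = FALSE)
  } else {
    if (x > design$n)
      stop("total responses cannot exceed the total sample size", call. = FALSE)
    if (x <= design$r1 && x > 0L)
      stop(sprintf(
        paste0("inconsistent outcome: a stage-2 total of %d cannot occur, ",
               "stage 1 requires more than r1 = %d responses to continue"),
        x, design$r1), call. = FALSE)
    if (x == 0L && design$r1 >= 0L)
      stop("inconsistent outcome: with x = 0 the trial must stop at stage 1",
           call. = FALSE)
  }
  structure(list(total_responses = x, stopped_stage1 = isTRUE(stopped_stage1),
                 design = design),
            class = "trial_outcome")
}

as_trial_outcome <- function(outcome, design) {
  if (inherits(outcome, "trial_outcome")) return(outcome)
  design <- as_two_stage_design(design)
  x <- as.integer(outcome)
  trial_outcome(x, design, stopped_stage1 = x <= design$r1)
}

#' Stage-wise p-value function of a two-stage outcome
#'
#' For a trial that reached stage 2 with `x` total responders this is
#' \deqn{Q(p) = \sum_{j=r_1+1}^{n_1} P(X_1 = j)\, P(X_2 \ge x - j),}
#' the probability of continuing to stage 2 and attaining at least the
#' observed total (`P(X2 >= k) = 1` for `k <= 0`). For a trial stopped at
#' stage 1 with `x1` responders it is `P(X1 >= x1)`. The observed outcome
#' is included in the tail. `Q` is continuous and non-decreasing in `p`;
#' evaluated at the null it is the design-adjusted p-value, and its roots
#' define the median-unbiased estimate and inverted confidence bounds.
#'
#' @param outcome A [trial_outcome()], or an integer total (a total
#'   `<= r1` is then interpreted as a stage-1 stop).
#' @param design A [two_stage_design()].
#' @param p Response probability at which to evaluate the tail.
#' @return The tail probability `Q(p)`.
#' @export
pvalue_function <- function(outcome, design, p) {
  design <- as_two_stage_design(design)
  outcome <- as_trial_outcome(outcome, design)
  p <- check_prob(p)
  x <- outcome$total_responses
  if (outcome$stopped_stage1)
    return(stats::pbinom(x - 1L, design$n1, p, lower.tail = FALSE))
  j <- (design$r1 + 1L):design$n1
  need <- x - j # need >= this many stage-2 responses
  tail2 <- ifelse(need <= 0, 1,
                  stats::pbinom(need - 1L, design$n2, p, lower.tail = FALSE))
  sum(stats::dbinom(j, design$n1, p) * tail2)
}

#' Design-adjusted p-value under the null response rate
#'
#' @inheritParams pvalue_function
#' @param p0 Null response probability.
#' @export
design_pvalue <- function(outcome, design, p0) {
  pvalue_function(outcome, design, p0)
}

# bisection for Q(p) = target; Q non-decreasing in p
invert_q <- function(outcome, design, target, tol = 1e-8, max_iter = 200L) {
  f <- function(p) pvalue_function(outcome, design, p) - target
  lo <- 0; hi <- 1
  flo <- f(0); fhi <- f(1)
  if (flo >= 0) return(0) # Q(0) already at/above target
  if (fhi <= 0) return(1)
  iter <- 0L
  while (hi - lo > tol && iter < max_iter) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  (lo + hi) / 2
}

#' Median-unbiased estimate of the response probability
#'
#' The response probability at which the stage-wise p-value function
#' [pvalue_function()] equals one half, found by bisection. Under the
#' stage-wise stochastic ordering this estimate is as likely to
#' overestimate as to underestimate the true response rate. An outcome of
#' zero responses returns 0 by convention.
#'
#' @inheritParams pvalue_function
#' @param tol Absolute bisection tolerance.
#' @export
median_unbiased_estimate <- function(outcome, design, tol = 1e-8) {
  design <- as_two_stage_design(design)
  outcome <- as_trial_outcome(outcome, design)
  if (outcome$total_responses == 0L) return(0)
  invert_q(outcome, design, 0.5, tol = tol)
}

#' Design-adjusted confidence interval by test inversion
#'
#' Inverts the stage-wise p-value function in the manner of Koyama and
#' Chen: with `gamma = (1 - conf_level)/2`, the lower bound solves
#' `Q(p) = gamma` and the upper bound solves `Q(p) = 1 - gamma`, each by
#' bisection; bounds are clipped to `[0, 1]`. Degenerate tails (zero
#' observed responses, where `Q` is identically one) return a lower bound
#' of 0 and an upper bound of 1.
#'
#' @inheritParams median_unbiased_estimate
#' @param conf_level Two-sided confidence level, e.g. `0.80`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(outcome, design, conf_level = 0.80,
                                tol = 1e-8) {
  design <- as_two_stage_design(design)
  outcome <- as_trial_outcome(outcome, design)
  if (length(conf_level) != 1L || !is.numeric(conf_level) ||
      conf_level <= 0 || conf_level >= 1)
    stop("'conf_level' must lie strictly between 0 and 1", call. = FALSE)
  gamma <- (1 - conf_level) / 2
  if (outcome$total_responses == 0L) return(c(lower = 0, upper = 1))
  c(lower = invert_q(outcome, design, gamma, tol = tol),
    upper = invert_q(outcome, design, 1 - gamma, tol = tol))
}

#' UMVUE of the response probability after a two-stage design
#'
#' The uniformly minimum-variance unbiased estimator given the two-stage
#' sampling rule. For a trial that reached stage 2 with total `x`:
#' \deqn{\hat p = \frac{\sum_j \binom{n_1-1}{j-1}\binom{n_2}{x-j}}
#'                    {\sum_j \binom{n_1}{j}\binom{n_2}{x-j}},}
#' with `j` ranging over `max(r1+1, x-n2) ... min(n1, x)`. For a trial
#' stopped at stage 1 the stage-1 proportion `x1/n1` is returned (the
#' UMVUE in that branch). Binomial coefficients are accumulated in
#' log-space for numerical stability.
#'
#' @inheritParams pvalue_function
#' @export
umvue <- function(outcome, design) {
  design <- as_two_stage_design(design)
  outcome <- as_trial_outcome(outcome, design)
  x <- outcome$total_responses
  if (outcome$stopped_stage1) return(x / design$n1)
  j <- max(design$r1 + 1L, x - design$n2):min(design$n1, x)
  lnum <- lchoose(design$n1 - 1L, j - 1L) + lchoose(design$n2, x - j)
  lden <- lchoose(design$n1, j) + lchoose(design$n2, x - j)
  m <- max(lden)
  sum(exp(lnum - m)) / sum(exp(lden - m))
}

#' Exact design-adjusted inference for an observed outcome
#'
#' Bundles the design-adjusted inference for one observed trial result:
#' median-unbiased point estimate, UMVUE, confidence interval by test
#' inversion, and the design-adjusted p-value under the null.
#'
#' @inheritParams pvalue_function
#' @param p0 Null response probability the p-value is computed against.
#' @param conf_level Two-sided confidence level for the interval.
#' @return An object of class `inference_result`: a list with `estimate`,
#'   `umvue`, `ci_lower`, `ci_upper`, `conf_level`, `p_value`,
#'   `total_responses` and the design.
#' @examples
#' d <- two_stage_design(0, 13, 2, 20)
#' design_inference(7, d, p0 = 0.05, conf_level = 0.80)
#' @export
design_inference <- function(outcome, design, p0, conf_level = 0.80) {
  design <- as_two_stage_design(design)
  outcome <- as_trial_outcome(outcome, design)
  ci <- confidence_interval(outcome, design, conf_level)
  structure(list(
    estimate = median_unbiased_estimate(outcome, design),
    umvue = umvue(outcome, design),
    ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
    conf_level = conf_level,
    p_value = design_pvalue(outcome, design, p0),
    p0 = p0,
    total_responses = outcome$total_responses,
    stopped_stage1 = outcome$stopped_stage1,
    design = design), class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("Design-adjusted inference (%d responses%s, design r1/n1 = %d/%d, r/n = %d/%d)\n",
              x$total_responses,
              if (x$stopped_stage1) ", stopped at stage 1" else "",
              x$design$r1, x$design$n1, x$design$r, x$design$n))
  cat(sprintf("  median-unbiased estimate: %.1f%%  (UMVUE %.1f%%)\n",
              round_half_up(100 * x$estimate, 1),
              round_half_up(100 * x$umvue, 1)))
  cat(sprintf("  %.0f%% CI: (%.1f%%, %.1f%%)\n", 100 * x$conf_level,
              round_half_up(100 * x$ci_lower, 1),
              round_half_up(100 * x$ci_upper, 1)))
  cat(sprintf("  p-value vs p0 = %g: %s\n", x$p0,
              format(signif(x$p_value, 4), scientific = TRUE)))
  invisible(x)
}
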