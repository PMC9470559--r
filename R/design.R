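#' Simon two-stage design object
#'
#' Construct the decision rule of a single-arm two-stage binomial trial.
#' Stage 1 enrols `n1` patients; if the number of responders is `<= r1`
#' accrual stops for futility. Otherwise a further `n2 = n - n1` patients
#' are enrolled and the null hypothesis is rejected (the trial is declared
#' a success) when the total number of responders exceeds `r`, i.e. when
#' at least `r + 1` responses are observed.
#'
#' @param r1 Stage-1 futility boundary (stop if stage-1 responses `<= r1`).
#' @param n1 Stage-1 sample size.
#' @param r Final rejection boundary (reject the null if total responses `> r`).
#' @param n Total sample size.
#' @return An object of class `two_stage_design` with elements `r1`, `n1`,
#'   `r`, `n` and the derived stage-2 size `n2`.
#' @examples
#' d <- two_stage_design(r1 = 0, n1 = 13, r = 2, n = 20)
#' reject_probability(d, 0.25)
#' @export
two_stage_design <- function(r1, n1, r, n) {
  for (v in list(r1 = r1, n1 = n1, r = r, n = n)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != round(v))
      stop("design parameters must be single integers", call. = FALSE)
  }
  r1 <- as.integer(r1); n1 <- as.integer(n1)
  r <- as.integer(r); n <- as.integer(n)
  if (r1 < 0L || r1 > n1) stop("need 0 <= r1 <= n1", call. = FALSE)
  if (n1 >= n) stop("need n1 < n (stage 2 must enrol at least one patient)",
                    call. = FALSE)
  if (r < r1 || r > n) stop("need r1 <= r <= n", call. = FALSE)
  structure(list(r1 = r1, n1 = n1, r = r, n = n, n2 = n - n1),
            class = "two_stage_design")
}

as_two_stage_design <- function(x) {
  if (inherits(x, "two_stage_design")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(two_stage_design(x[[1]], x[[2]], x[[3]], x[[4]]))
  if (is.list(x) && all(c("r1", "n1", "r", "n") %in% names(x)))
    return(two_stage_design(x$r1, x$n1, x$r, x$n))
  stop("cannot interpret 'design'; supply two_stage_design() or c(r1,n1,r,n)",
       call. = FALSE)
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat(sprintf(
    "Simon two-stage design: r1 = %d, n1 = %d, r = %d, n = %d (n2 = %d)\n",
    x$r1, x$n1, x$r, x$n, x$n2))
  cat(sprintf(
    "  stop for futility if stage-1 responses <= %d; success if total >= %d\n",
    x$r1, x$r + 1L))
  invisible(x)
}

check_prob <- function(p, what = "p") {
  if (length(p) != 1L || !is.numeric(p) || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", what),
         call. = FALSE)
  as.numeric(p)
}

#' Exact rejection probability of a two-stage design
#'
#' Probability that the trial continues past stage 1 and the total response
#' count exceeds the rejection boundary, \eqn{P(X_1 > r_1, X_1 + X_2 > r)}
#' with \eqn{X_1 \sim Bin(n_1, p)} and \eqn{X_2 \sim Bin(n_2, p)}, computed
#' by exact summation over the stage-1 outcomes (no normal approximation).
#' Evaluated at the null response rate this is the attained one-sided type-I
#' error; at the alternative it is the attained power.
#'
#' @param design A [two_stage_design()].
#' @param p True per-patient response probability.
#' @return The exact rejection probability.
#' @export
reject_probability <- function(design, p) {
  design <- as_two_stage_design(design)
  p <- check_prob(p)
  if (design$r1 >= design$n1) return(0)
  x1 <- (design$r1 + 1L):design$n1
  need <- design$r - x1 # reject iff X2 > need
  tail2 <- ifelse(need < 0, 1,
                  stats::pbinom(need, design$n2, p, lower.tail = FALSE))
  sum(stats::dbinom(x1, design$n1, p) * tail2)
}

#' Probability of early termination
#'
#' Probability that accrual stops at the end of stage 1,
#' \eqn{P(X_1 \le r_1)} under \eqn{Bin(n_1, p)}.
#'
#' @inheritParams reject_probability
#' @export
prob_early_termination <- function(design, p) {
  design <- as_two_stage_design(design)
  p <- check_prob(p)
  stats::pbinom(design$r1, design$n1, p)
}

#' Expected sample size of a two-stage design
#'
#' \eqn{E[N] = n_1 + (1 - PET(p)) \, n_2}, where PET is the probability of
#' early termination at response probability `p`.
#'
#' @inheritParams reject_probability
#' @export
expected_sample_size <- function(design, p) {
  design <- as_two_stage_design(design)
  p <- check_prob(p)
  design$n1 + (1 - prob_early_termination(design, p)) * design$n2
}

#' Exact operating characteristics of a design
#'
#' @inheritParams reject_probability
#' @param p0 Null (unacceptable) response probability.
#' @param p1 Alternative (target) response probability.
#' @return A list with `attained_alpha` (rejection probability at `p0`),
#'   `attained_power` (at `p1`), `pet_p0` and `expected_n_p0`.
#' @export
design_properties <- function(design, p0, p1) {
  design <- as_two_stage_design(design)
  list(attained_alpha = reject_probability(design, p0),
       attained_power = reject_probability(design, p1),
       pet_p0         = prob_early_termination(design, p0),
       expected_n_p0  = expected_sample_size(design, p0))
}

#' Search for Simon minimax and optimal two-stage designs
#'
#' Exhaustively enumerates two-stage designs `(r1, n1, r, n)` with total
#' size up to `n_max` and retains those whose exact type-I error at `p0`
#' is at most `alpha` and whose exact power at `p1` is at least
#' `1 - beta`. The minimax design is the feasible design with the smallest
#' total `n` (ties broken by smallest expected sample size under `p0`,
#' then smallest `n1`); the optimal design minimises the expected sample
#' size under `p0` over all feasible designs.
#'
#' For each `(n, n1, r1)` the smallest alpha-feasible rejection boundary
#' `r` is located by bisection over the (monotone decreasing in `r`)
#' rejection probability; that boundary also maximises power among the
#' alpha-feasible ones, so only it needs to be checked. Stage-1 boundaries
#' with early-stopping probability under `p1` above `beta` cannot reach the
#' power target and are pruned.
#'
#' @param p0 Unacceptable response probability (null).
#' @param p1 Target response probability; must exceed `p0`.
#' @param alpha One-sided type-I error bound.
#' @param beta Type-II error bound (power target is `1 - beta`).
#' @param n_max Ceiling on the total sample size searched.
#' @return A list of class `simon_search` with elements `minimax` and
#'   `optimal`, each a [two_stage_design()] carrying its
#'   [design_properties()] in attribute-free list fields `properties`,
#'   plus the search settings.
#' @examples
#' \donttest{
#' s <- search_designs(p0 = 0.05, p1 = 0.25, alpha = 0.10, beta = 0.10,
#'                     n_max = 60)
#' s$minimax$design
#' }
#' @export
search_designs <- function(p0, p1, alpha, beta, n_max = 150) {
  p0 <- check_prob(p0, "p0"); p1 <- check_prob(p1, "p1")
  alpha <- check_prob(alpha, "alpha"); beta <- check_prob(beta, "beta")
  if (p0 >= p1) stop("need p0 < p1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("alpha and beta must lie strictly between 0 and 1", call. = FALSE)
  if (length(n_max) != 1L || !is.numeric(n_max) || n_max < 2)
    stop("'n_max' must be a single integer >= 2", call. = FALSE)
  n_max <- as.integer(n_max)

  best_minimax <- NULL # list(design, props)
  best_optimal <- NULL
  best_en <- Inf

  rej <- function(r1, n1, n2, r, p) {
    x1 <- (r1 + 1L):n1
    need <- r - x1
    tail2 <- ifelse(need < 0, 1, stats::pbinom(need, n2, p, lower.tail = FALSE))
    sum(stats::dbinom(x1, n1, p) * tail2)
  }

  for (n in 2:n_max) {
    for (n1 in seq_len(n - 1L)) {
      n2 <- n - n1
      # once a feasible design exists, (n1, r1) pairs whose best-case
      # expected size already exceeds the incumbent cannot improve either
      # criterion at this or any larger n1
      if (!is.null(best_minimax) && n1 >= best_en) break
      pet1 <- stats::pbinom(0:n1, n1, p1)
      pet0 <- stats::pbinom(0:n1, n1, p0)
      for (r1 in 0:(n1 - 1L)) {
        if (pet1[r1 + 1L] > beta) break # power unreachable; larger r1 worse
        en <- n1 + (1 - pet0[r1 + 1L]) * n2
        if (!is.null(best_minimax) && n > best_minimax$design$n &&
            en >= best_en) next
        # smallest r with attained alpha <= alpha (alpha decreasing in r)
        lo <- r1; hi <- n
        if (rej(r1, n1, n2, lo, p0) <= alpha) {
          r <- lo
        } else {
          while (hi - lo > 1L) {
            mid <- (lo + hi) %/% 2L
            if (rej(r1, n1, n2, mid, p0) <= alpha) hi <- mid else lo <- mid
          }
          r <- hi
        }
        power <- rej(r1, n1, n2, r, p1)
        if (power < 1 - beta) next
        cand <- list(
          design = two_stage_design(r1, n1, r, n),
          properties = list(
            attained_alpha = rej(r1, n1, n2, r, p0),
            attained_power = power,
            pet_p0 = pet0[r1 + 1L],
            expected_n_p0 = en))
        if (is.null(best_minimax)) {
          best_minimax <- cand
        } else if (n == best_minimax$design$n &&
                   (en < best_minimax$properties$expected_n_p0 -
                      1e-12)) {
          best_minimax <- cand
        }
        if (en < best_en - 1e-12) {
          best_optimal <- cand
          best_en <- en
        }
      }
    }
  }
  if (is.null(best_minimax))
    stop(sprintf(
      "search ceiling exceeded: no design with n <= %d attains alpha <= %g and power >= %g",
      n_max, alpha, 1 - beta), call. = FALSE)
  structure(list(minimax = best_minimax, optimal = best_optimal,
                 spec = list(p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                             n_max = n_max)),
            class = "simon_search")
}

#' @export
print.simon_search <- function(x, ...) {
  cat(sprintf("Simon two-stage design search: p0 = %g, p1 = %g, alpha = %g, beta = %g (n_max = %d)\n\n",
              x$spec$p0, x$spec$p1, x$spec$alpha, x$spec$beta, x$spec$n_max))
  for (which in c("minimax", "optimal")) {
    d <- x[[which]]$design; pr <- x[[which]]$properties
    cat(sprintf("%s: r1/n1 = %d/%d, r/n = %d/%d | alpha = %.4f, power = %.4f, PET(p0) = %.4f, EN(p0) = %.2f\n",
                which, d$r1, d$n1, d$r, d$n,
                pr$attained_alpha, pr$attained_power, pr$pet_p0,
                pr$expected_n_p0))
  }
  invisible(x)
}
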