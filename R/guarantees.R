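#' Privacy-accuracy calculators for choosing epsilon and tau
#'
#' Closed-form helpers translating a policymaker's accuracy requirements
#' into the smallest admissible privacy loss parameter, and an existing
#' organizational suppression standard into a threshold tau.
#'
#' * `heuristic_epsilon_for_error()` uses the standard deviation of the
#'   Laplace noise, T*sqrt(2)/epsilon: if the typical per-cell error must
#'   not exceed `alpha`, any epsilon >= sqrt(2)*T/alpha suffices.
#' * `epsilon_for_error_bound()` uses the noise tail instead of its
#'   standard deviation: it returns the smallest epsilon such that, with
#'   probability at least 1 - delta, a released (rounded) non-suppressed
#'   cell differs from the true count by at most `alpha`; the half-unit
#'   term accounts for integer rounding. It permits a larger epsilon than
#'   the heuristic for the same alpha, i.e. a more accurate release.
#' * `laplace_cell_std()` is the per-cell noise standard deviation
#'   T*sqrt(2)/epsilon itself.
#' * `tau_from_standard()` adapts an organizational suppression standard
#'   `s` to the noise: unchanged keeps tau = s; minimize-suppression sets
#'   tau = s - sqrt(2)/epsilon (clamped at 0) so fewer cells are withheld;
#'   maximize-protection sets tau = s + sqrt(2)/epsilon so noise is less
#'   likely to surface small sub-populations. Results are rounded to
#'   non-negative integers.
#'
#' @param alpha Error tolerance on a single O-D cell (trips), > 0 for the
#'   heuristic, >= 0 for the tail bound.
#' @param T Positive integer contribution bound (1 = trip level).
#' @param delta Failure probability in (0, 1].
#' @param epsilon Privacy loss parameter, > 0.
#' @param s Non-negative organizational suppression standard.
#' @param direction One of `"unchanged"`, `"minimize-suppression"`,
#'   `"maximize-protection"`.
#' @return A single number: the minimal epsilon, the noise standard
#'   deviation, or the integer threshold tau.
#' @examples
#' heuristic_epsilon_for_error(alpha = 10)        # ~0.14
#' epsilon_for_error_bound(alpha = 10, delta = 0.05)  # ~0.285
#' tau_from_standard(s = 15, epsilon = 0.5, "maximize-protection")
#' @export
heuristic_epsilon_for_error <- function(alpha, T = 1) {
  check_number(alpha, "alpha", lower = 0, strict = TRUE)
  check_number(T, "T", lower = 1)
  sqrt(2) * T / alpha
}

#' @rdname heuristic_epsilon_for_error
#' @export
epsilon_for_error_bound <- function(alpha, delta, T = 1) {
  check_number(alpha, "alpha", lower = 0)
  check_number(T, "T", lower = 1)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1) {
    abort("`delta` must be in (0, 1].")
  }
  -T * log(delta) / (alpha + 0.5)
}

#' @rdname heuristic_epsilon_for_error
#' @export
laplace_cell_std <- function(T = 1, epsilon) {
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  check_number(T, "T", lower = 1)
  T * sqrt(2) / epsilon
}

#' @rdname heuristic_epsilon_for_error
#' @export
tau_from_standard <- function(s, epsilon,
                              direction = c("unchanged", "minimize-suppression",
                                            "maximize-protection")) {
  check_number(s, "s", lower = 0)
  direction <- match.arg(direction)
  if (direction != "unchanged") check_number(epsilon, "epsilon", 0, strict = TRUE)
  tau <- switch(direction,
    "unchanged" = s,
    "minimize-suppression" = s - sqrt(2) / epsilon,
    "maximize-protection" = s + sqrt(2) / epsilon
  )
  max(0, round_half_up(tau))
}

#' Suppression probability of a cell under the release mechanism
#'
#' The probability that a cell with true count `true_count` is suppressed,
#' i.e. that count + Laplace(T/epsilon) falls below tau, via the Laplace
#' CDF. A cell sitting exactly at the threshold is suppressed with
#' probability 1/2 (symmetric noise).
#'
#' @param true_count Non-negative true cell count.
#' @param tau Suppression threshold.
#' @param epsilon Privacy loss parameter, > 0.
#' @param T Contribution bound.
#' @return Probability in \[0, 1\]; vectorised over `true_count`.
#' @export
suppression_probability <- function(true_count, tau, epsilon, T = 1) {
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  laplace_cdf(tau - true_count, scale = T / epsilon)
}

#' Monte-Carlo error of a privatized between-period difference
#'
#' Policymakers often compare counts across periods (e.g. out-migration
#' before vs after a shock). This simulates the two counts being released
#' independently with Laplace(T/epsilon) noise (no suppression), and
#' returns the Monte-Carlo mean absolute error of the released difference
#' against the true difference. The error shrinks as epsilon grows,
#' following a Theta(epsilon * exp(-epsilon)) decay in the detection
#' regime.
#'
#' @param count_pair Numeric length-2 vector of the two true counts.
#' @param epsilon Privacy loss parameter, > 0.
#' @param T Contribution bound.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Optional integer seed.
#' @return Mean absolute error (a single number).
#' @export
difference_detection_error <- function(count_pair, epsilon, T = 1,
                                       reps = 1e4, seed = NULL) {
  stopifnot(length(count_pair) == 2)
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  check_number(reps, "reps", lower = 1)
  scale <- T / epsilon
  with_seed_opt(seed, {
    a <- dp_release_counts(rep(count_pair[1], reps), scale, tau = 0)$released
    b <- dp_release_counts(rep(count_pair[2], reps), scale, tau = 0)$released
    mean(abs((a - b) - (count_pair[1] - count_pair[2])))
  })
}
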