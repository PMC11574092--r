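#' Empirical differential-privacy audit of the release mechanism
#'
#' Checks the epsilon-DP guarantee of the count release empirically on a
#' pair of neighboring datasets. Under trip-level protection (T = 1),
#' adding or removing one trip changes exactly one O-D cell by 1 while all
#' other cells keep identical release distributions, so the audit reduces
#' to that one cell: the mechanism is run `reps` times on the true count
#' `count` and on the neighboring count `count + 1`, the discrete outputs
#' (suppressed, or an integer >= tau) are tallied, and the largest absolute
#' log-ratio of the two empirical output distributions is compared with the
#' theoretical bound epsilon.
#'
#' Output categories observed fewer than `min_count` times in either arm
#' are excluded from the ratio, since their empirical ratio is dominated by
#' Monte-Carlo noise rather than the mechanism.
#'
#' @param count True cell count in the first dataset; the neighboring
#'   dataset has `count + 1` (one extra trip).
#' @param epsilon Privacy loss parameter being audited, > 0.
#' @param tau Suppression threshold used in the release.
#' @param reps Number of mechanism runs per arm.
#' @param min_count Minimum tally in both arms for a category to enter the
#'   ratio.
#' @param seed Optional integer seed.
#' @return A list of class `dp_audit`: `epsilon`, the per-category tally
#'   tibble, `max_log_ratio` (empirical), and `bound_satisfied` — whether
#'   the empirical maximum stays within epsilon plus three binomial
#'   standard errors.
#' @examples
#' audit_dp_mechanism(count = 2, epsilon = 1, tau = 2, reps = 1e5, seed = 1)
#' @export
audit_dp_mechanism <- function(count, epsilon, tau = 0, reps = 1e6,
                               min_count = 25, seed = NULL) {
  check_number(count, "count", lower = 0)
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  check_number(reps, "reps", lower = 1)
  scale <- 1 / epsilon # T = 1: trip-level sensitivity
  with_seed_opt(seed, {
    a <- dp_release_counts(rep(count, reps), scale, tau)
    b <- dp_release_counts(rep(count + 1, reps), scale, tau)
    cat_a <- ifelse(a$suppressed, "suppressed", as.character(a$released))
    cat_b <- ifelse(b$suppressed, "suppressed", as.character(b$released))
    cats <- union(unique(cat_a), unique(cat_b))
    tab <- tibble::tibble(
      output = cats,
      n_a = as.integer(table(factor(cat_a, cats))),
      n_b = as.integer(table(factor(cat_b, cats)))
    ) |>
      dplyr::mutate(
        p_a = .data$n_a / reps,
        p_b = .data$n_b / reps,
        log_ratio = log(.data$p_a) - log(.data$p_b),
        usable = .data$n_a >= min_count & .data$n_b >= min_count
      )
    used <- dplyr::filter(tab, .data$usable)
    max_lr <- max(abs(used$log_ratio))
    # 3-sigma Monte-Carlo allowance on the worst category's log-ratio
    worst <- used[which.max(abs(used$log_ratio)), ]
    se <- sqrt((1 - worst$p_a) / worst$n_a + (1 - worst$p_b) / worst$n_b)
    structure(
      list(
        epsilon = epsilon, count = count, tau = tau, reps = reps,
        categories = tab,
        max_log_ratio = max_lr,
        mc_allowance = 3 * se,
        bound_satisfied = max_lr <= epsilon + 3 * se
      ),
      class = "dp_audit"
    )
  })
}

#' @export
print.dp_audit <- function(x, ...) {
  cat(sprintf(
    "<dp_audit> epsilon = %g (counts %d vs %d, tau = %d, %g runs/arm)\n",
    x$epsilon, x$count, x$count + 1, x$tau, x$reps
  ))
  cat(sprintf(
    "  max |log ratio| = %.4f vs bound %.4f (+%.4f MC allowance): %s\n",
    x$max_log_ratio, x$epsilon, x$mc_allowance,
    if (x$bound_satisfied) "within bound" else "VIOLATED"
  ))
  invisible(x)
}

#' @export
tidy.dp_audit <- function(x, ...) x$categories

#' @export
glance.dp_audit <- function(x, ...) {
  tibble::tibble(
    epsilon = x$epsilon, reps = x$reps,
    max_log_ratio = x$max_log_ratio,
    mc_allowance = x$mc_allowance,
    bound_satisfied = x$bound_satisfied
  )
}
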