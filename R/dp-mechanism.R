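#' Privacy parameters of a release
#'
#' Bundles the parameters of the differentially private O-D release: the
#' privacy loss parameter epsilon, the contribution bound T, the
#' suppression threshold tau, and the seed of the release.
#'
#' `T` has two readings. With `T = 1` the release protects individual
#' *trips*: adding or removing any one trip changes any count by at most 1.
#' With `T > 1`, after censoring each subscriber to at most T trips
#' ([censor_trips()]), the release protects *individuals*, whose total
#' contribution is bounded by T. In both cases the Laplace noise scale is
#' T/epsilon.
#'
#' @param epsilon Privacy loss parameter, > 0. Smaller is more private and
#'   noisier.
#' @param T Positive integer contribution bound (sensitivity).
#' @param tau Non-negative integer suppression threshold: noised counts
#'   below tau are withheld (released as 0 and flagged).
#' @param seed Optional integer seed governing the whole release.
#' @return An object of class `privacy_params`.
#' @examples
#' privacy_params(epsilon = 0.5, T = 1, tau = 15)
#' @export
privacy_params <- function(epsilon, T = 1, tau = 0, seed = NULL) {
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  check_number(T, "T", lower = 1)
  check_number(tau, "tau", lower = 0)
  structure(
    list(epsilon = epsilon, T = as.integer(T), tau = as.integer(tau), seed = seed),
    class = "privacy_params"
  )
}

#' @export
print.privacy_params <- function(x, ...) {
  cat(sprintf(
    "<privacy_params> epsilon = %g, T = %d (%s-level), tau = %d%s\n",
    x$epsilon, x$T, if (x$T == 1) "trip" else "individual", x$tau,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)
  ))
  invisible(x)
}

#' Censor per-subscriber trip contributions
#'
#' Preprocessing for individual-level protection: any subscriber with more
#' than `T` trips has `T` of them kept, selected uniformly at random
#' without replacement; subscribers with at most `T` trips keep all of
#' them. After censoring, no individual contributes more than `T` trips to
#' any subsequent release.
#'
#' @param trips Tibble of trips (`subscriber_id`, `day`, `origin`,
#'   `destination`).
#' @param T Positive integer cap on per-subscriber trips.
#' @param seed Optional integer seed for reproducible selection.
#' @return A tibble containing a subset of the rows of `trips`.
#' @export
censor_trips <- function(trips, T, seed = NULL) {
  check_number(T, "T", lower = 1)
  with_seed_opt(seed, {
    trips |>
      dplyr::group_by(.data$subscriber_id) |>
      dplyr::slice_sample(n = as.integer(T)) |>
      dplyr::ungroup()
  })
}

# Core release kernel shared by the matrix mechanism and the empirical
# audit: adds Laplace(scale) noise to each count, suppresses strictly
# below tau, otherwise rounds half-up and clamps at tau.
dp_release_counts <- function(counts, scale, tau) {
  noisy <- counts + sample_laplace(scale, length(counts))
  suppressed <- noisy < tau
  released <- pmax(round_half_up(noisy), tau, 0)
  released[suppressed] <- 0
  list(released = released, suppressed = suppressed)
}

#' Differentially private release of an O-D matrix
#'
#' The release mechanism: (1) the daily inter-region counts are taken as
#' given (censor contributions first with [censor_trips()] if
#' individual-level protection at `T > 1` is intended); (2) independent
#' Laplace noise with scale T/epsilon is added to every off-diagonal cell;
#' (3) cells whose noised value falls strictly below the threshold tau are
#' suppressed — released as 0 and flagged — while the remaining cells are
#' rounded half-up to integers and clamped at tau. Every released
#' non-suppressed value is therefore an integer of at least tau, no
#' released value is ever negative, and the diagonal stays zero.
#'
#' @param m An [od_matrix].
#' @param params A [privacy_params] object.
#' @return A `private_od_matrix`: the released counts, the suppression
#'   flags, and `params`.
#' @examples
#' m <- od_matrix(matrix(c(0, 40, 3, 0), 2, 2, byrow = TRUE), c("A", "B"),
#'                day = "2020-01-01")
#' privatize_od_matrix(m, privacy_params(epsilon = 0.5, tau = 15, seed = 1))
#' @export
privatize_od_matrix <- function(m, params) {
  stopifnot(inherits(m, "od_matrix"), inherits(params, "privacy_params"))
  k <- length(m$regions)
  off <- which(row(m$counts) != col(m$counts))
  scale <- params$T / params$epsilon
  rel <- with_seed_opt(params$seed,
    dp_release_counts(m$counts[off], scale, params$tau)
  )
  counts <- matrix(0, k, k)
  suppressed <- matrix(FALSE, k, k)
  counts[off] <- rel$released
  suppressed[off] <- rel$suppressed
  new_private_od_matrix(m, counts, suppressed, params)
}

#' Differentially private release of a count vector
#'
#' Privatizes per-region counts (e.g. the inferred regional populations
#' used as SIR denominators) with Laplace noise of scale 1/epsilon, no
#' suppression, rounding to integers and clamping at 1 so the result is
#' always usable as a denominator.
#'
#' @param values Non-negative numeric vector of counts.
#' @param epsilon Privacy loss parameter, > 0.
#' @param seed Optional integer seed.
#' @return Numeric vector of the same length, integer-valued, >= 1.
#' @export
privatize_count_vector <- function(values, epsilon, seed = NULL) {
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  if (any(values < 0)) abort("`values` must be non-negative.")
  with_seed_opt(seed, {
    noisy <- values + sample_laplace(1 / epsilon, length(values))
    pmax(round_half_up(noisy), 1)
  })
}
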