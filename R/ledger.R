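#' Privacy-loss ledger
#'
#' Tracks the cumulative privacy loss of a sequence of releases under
#' linear composition. Two regimes are supported:
#'
#' * **trip-level** (`T = 1`): each released daily matrix costs an
#'   individual `epsilon * n_j`, where `n_j` is the number of their trips
#'   appearing in release j; over J releases the loss is
#'   `epsilon * (n_1 + ... + n_J)`.
#' * **individual-level** (censored at T): each release costs `epsilon`
#'   regardless of trip counts, so J releases cost `epsilon * J`.
#'
#' `record_release()` appends one release; `total_privacy_loss()` returns
#' the accumulated loss, which is additive over concatenated ledgers.
#' `expected_privacy_loss()` is the population-average counterpart for the
#' trip-level regime: epsilon times the mean number of trips an individual
#' contributes over the whole window.
#'
#' @param regime `"trip-level"` or `"individual-level"`.
#' @param epsilon Per-release privacy loss parameter, > 0.
#' @return `privacy_ledger()` returns an empty ledger (class
#'   `privacy_ledger`); `record_release()` returns the extended ledger.
#' @examples
#' led <- privacy_ledger("trip-level", epsilon = 0.5)
#' led <- record_release(led, n = 14)
#' total_privacy_loss(led) # 7
#' @export
privacy_ledger <- function(regime = c("trip-level", "individual-level"), epsilon) {
  regime <- match.arg(regime)
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  structure(
    list(
      regime = regime, epsilon = epsilon,
      releases = tibble::tibble(
        release = integer(), epsilon = double(), n = double(), loss = double()
      )
    ),
    class = "privacy_ledger"
  )
}

#' @rdname privacy_ledger
#' @param ledger A `privacy_ledger`.
#' @param n For the trip-level regime, the (maximum or average) number of
#'   trips the tracked individual contributes to this release; ignored in
#'   the individual-level regime, where each release costs epsilon.
#' @export
record_release <- function(ledger, n = NA_real_) {
  stopifnot(inherits(ledger, "privacy_ledger"))
  if (ledger$regime == "trip-level") {
    if (is.na(n) || n < 0) abort("trip-level releases need a contribution count n >= 0.")
    loss <- ledger$epsilon * n
  } else {
    n <- NA_real_
    loss <- ledger$epsilon
  }
  ledger$releases <- dplyr::bind_rows(
    ledger$releases,
    tibble::tibble(
      release = nrow(ledger$releases) + 1L,
      epsilon = ledger$epsilon, n = n, loss = loss
    )
  )
  ledger
}

#' @rdname privacy_ledger
#' @export
total_privacy_loss <- function(ledger) {
  stopifnot(inherits(ledger, "privacy_ledger"))
  sum(ledger$releases$loss)
}

#' @rdname privacy_ledger
#' @param a,b Ledgers of the same regime and epsilon to concatenate; the
#'   total loss of the result is the sum of the two.
#' @export
concat_ledgers <- function(a, b) {
  stopifnot(inherits(a, "privacy_ledger"), inherits(b, "privacy_ledger"))
  if (a$regime != b$regime || a$epsilon != b$epsilon) {
    abort("Ledgers must share regime and epsilon to concatenate.")
  }
  a$releases <- dplyr::bind_rows(a$releases, b$releases)
  a$releases$release <- seq_len(nrow(a$releases))
  a
}

#' Expected (population-average) privacy loss of a release window
#'
#' Under trip-level protection the worst-case loss over a window is
#' epsilon times an individual's total trips; averaging over the
#' population gives epsilon times the mean per-subscriber trip total.
#'
#' @param epsilon Per-release privacy loss parameter.
#' @param mean_trips_total Average per-subscriber number of trips over the
#'   whole release window, >= 0.
#' @return Expected privacy loss (a single number).
#' @examples
#' expected_privacy_loss(0.5, 2.88) # 1.44
#' @export
expected_privacy_loss <- function(epsilon, mean_trips_total) {
  check_number(epsilon, "epsilon", lower = 0, strict = TRUE)
  check_number(mean_trips_total, "mean_trips_total", lower = 0)
  epsilon * mean_trips_total
}

#' @export
print.privacy_ledger <- function(x, ...) {
  cat(sprintf(
    "<privacy_ledger> %s, epsilon = %g, %d release(s), total loss = %g\n",
    x$regime, x$epsilon, nrow(x$releases), total_privacy_loss(x)
  ))
  invisible(x)
}

#' @export
tidy.privacy_ledger <- function(x, ...) {
  dplyr::mutate(x$releases,
    regime = x$regime,
    cumulative_loss = cumsum(.data$loss),
    .before = 1
  )
}

#' @export
glance.privacy_ledger <- function(x, ...) {
  tibble::tibble(
    regime = x$regime, epsilon = x$epsilon,
    n_releases = nrow(x$releases),
    total_loss = total_privacy_loss(x)
  )
}
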