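#' Per-cell error of a private O-D matrix release
#'
#' Compares a private release to its non-private source, cell by cell.
#' Absolute error is |private - nonprivate| with suppressed cells read at
#' their released value of 0. Relative error is the symmetric form
#' 2|private - nonprivate| / (private + nonprivate), which lies in
#' \[0, 2\] and is defined as 0 when both counts are 0. Medians are taken
#' over the off-diagonal cells.
#'
#' @param private A `private_od_matrix`.
#' @param nonprivate The matching [od_matrix] (same regions and day).
#' @return A tibble of off-diagonal cells with columns `origin`,
#'   `destination`, `private`, `nonprivate`, `suppressed`, `abs_error`,
#'   `rel_error`, carrying the medians as attributes; `glance()` returns
#'   them as a one-row tibble (`median_abs_error`, `median_rel_error`).
#' @export
matrix_error_summary <- function(private, nonprivate) {
  stopifnot(inherits(private, "private_od_matrix"), inherits(nonprivate, "od_matrix"))
  if (!identical(private$regions, nonprivate$regions)) {
    abort("Private and non-private matrices cover different regions.")
  }
  off <- which(row(private$counts) != col(private$counts))
  p <- private$counts[off]
  q <- nonprivate$counts[off]
  abs_err <- abs(p - q)
  rel_err <- ifelse(p + q == 0, 0, 2 * abs_err / (p + q))
  supp <- private$suppressed[off]
  out <- tibble::tibble(
    origin = private$regions[row(private$counts)[off]],
    destination = private$regions[col(private$counts)[off]],
    private = p, nonprivate = q,
    suppressed = supp,
    abs_error = abs_err, rel_error = rel_err
  )
  attr(out, "median_abs_error") <- median(abs_err)
  attr(out, "median_rel_error") <- median(rel_err)
  class(out) <- c("od_error_summary", class(out))
  out
}

#' @export
glance.od_error_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_suppressed = sum(x$suppressed),
    median_abs_error = attr(x, "median_abs_error"),
    median_rel_error = attr(x, "median_rel_error")
  )
}

#' Accuracy, precision and recall of private intervention decisions
#'
#' Compares the per-region, per-day binary intervention decisions made
#' from private data against those made from non-private data (the ground
#' truth). For each region, over all days: accuracy is the fraction of
#' days agreeing; precision is TP/(TP+FP); recall is TP/(TP+FN). Regions
#' with no ground-truth positives contribute recall = 1, and precision = 1
#' when they also predict no positives (0 when they predict some). Regions
#' with positives but no predicted positives contribute precision = 0.
#' Means and standard deviations are taken across regions with equal
#' weight.
#'
#' @param private_decisions,nonprivate_decisions Tibbles from
#'   [policy_decisions()] (`day`, `region`, `decision`) over the same
#'   region-day grid.
#' @return A list with `by_region` (tibble `region`, `accuracy`,
#'   `precision`, `recall`) and `summary` (tibble of means and standard
#'   deviations across regions).
#' @export
decision_metrics <- function(private_decisions, nonprivate_decisions) {
  joined <- dplyr::inner_join(
    private_decisions, nonprivate_decisions,
    by = c("day", "region"), suffix = c("_priv", "_true")
  )
  if (nrow(joined) != nrow(private_decisions) ||
      nrow(joined) != nrow(nonprivate_decisions)) {
    abort("Decision grids do not cover the same region-day cells.")
  }
  by_region <- joined |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      tp = sum(.data$decision_priv == 1 & .data$decision_true == 1),
      fp = sum(.data$decision_priv == 1 & .data$decision_true == 0),
      fn = sum(.data$decision_priv == 0 & .data$decision_true == 1),
      tn = sum(.data$decision_priv == 0 & .data$decision_true == 0)
    ) |>
    dplyr::mutate(
      accuracy = (.data$tp + .data$tn) / (.data$tp + .data$fp + .data$fn + .data$tn),
      precision = dplyr::case_when(
        .data$tp + .data$fp > 0 ~ .data$tp / (.data$tp + .data$fp),
        .data$fn == 0 ~ 1, # no positives anywhere: vacuously correct
        TRUE ~ 0           # positives existed but none predicted
      ),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), 1)
    ) |>
    dplyr::select("region", "accuracy", "precision", "recall")
  summary <- by_region |>
    tidyr::pivot_longer(-"region", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value)) |>
    dplyr::arrange(match(.data$metric, c("accuracy", "precision", "recall")))
  list(by_region = by_region, summary = summary)
}

#' Percent error of a private total against the non-private total
#'
#' @param private_total,nonprivate_total Totals from the private and
#'   non-private windows; the non-private total (the denominator) must be
#'   positive.
#' @return `100 * |nonprivate - private| / nonprivate`.
#' @examples
#' percent_error(30595, 32627) # ~6.23
#' @export
percent_error <- function(private_total, nonprivate_total) {
  check_number(nonprivate_total, "nonprivate_total", lower = 0, strict = TRUE)
  100 * abs(nonprivate_total - private_total) / nonprivate_total
}

#' Top-k selection accuracy of private matrices
#'
#' For each day in the window, the k regions receiving the most migrants
#' from the affected region are selected from the private and the
#' non-private matrix separately; the day's accuracy is the overlap of the
#' two selections divided by k. The window accuracy is the mean over days,
#' as a percentage.
#'
#' @param private_matrices,nonprivate_matrices Lists of matrices over the
#'   same window (same length and day order).
#' @param affected Affected region id.
#' @param k Number of regions selected per day.
#' @param mode Passed to [top_k_flows()].
#' @return Percentage in \[0, 100\].
#' @export
topk_accuracy <- function(private_matrices, nonprivate_matrices, affected,
                          k = 3, mode = "destinations") {
  if (length(private_matrices) != length(nonprivate_matrices)) {
    abort("Private and non-private windows have different lengths.")
  }
  daily <- purrr::map2_dbl(private_matrices, nonprivate_matrices, function(p, q) {
    sp <- top_k_flows(list(p), affected, k, mode)$region
    sq <- top_k_flows(list(q), affected, k, mode)$region
    length(intersect(sp, sq)) / k
  })
  100 * mean(daily)
}
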