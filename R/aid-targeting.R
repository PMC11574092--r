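#' Total out-migration over a response window
#'
#' Sums out-flows over a window of daily O-D matrices: with an affected
#' region, the row of that region (all trips leaving it) summed over days;
#' in all-regions mode, the grand total of every matrix. Suppressed cells
#' of private matrices contribute 0 (their released value), which is why
#' private totals are biased downwards relative to non-private ones.
#'
#' @param matrices List of [od_matrix] (or `private_od_matrix`) objects
#'   over the response window.
#' @param affected Region id of the affected area, or `NULL` for the
#'   all-regions grand total.
#' @return Total trips (a single number).
#' @export
total_out_migration <- function(matrices, affected = NULL) {
  if (inherits(matrices, "od_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0) abort("Window of O-D matrices is empty.")
  if (is.null(affected)) {
    return(sum(purrr::map_dbl(matrices, od_total)))
  }
  regions <- matrices[[1]]$regions
  if (!affected %in% regions) {
    abort(sprintf("Unknown region '%s'.", affected))
  }
  sum(purrr::map_dbl(matrices, ~ sum(.x$counts[affected, ])))
}

#' Top-k regions of out-migration
#'
#' Ranks regions by migration flow over a window of daily O-D matrices and
#' returns the k largest. In `"destinations"` mode (the default,
#' matching the aid-targeting question "which regions receive the most
#' migrants from the affected area?") regions are ranked by the total flow
#' received from `affected`; in `"origins"` mode, by their own total
#' out-flow. Ties are broken by region id ascending, so the result is
#' deterministic and invariant to input order.
#'
#' @inheritParams total_out_migration
#' @param affected Region id of the affected area (excluded from the
#'   candidates in destinations mode).
#' @param k Number of regions to select, >= 1.
#' @param mode `"destinations"` or `"origins"`.
#' @return Tibble with columns `rank`, `region`, `flow`, k rows, in rank
#'   order.
#' @export
top_k_flows <- function(matrices, affected, k = 3,
                        mode = c("destinations", "origins")) {
  if (inherits(matrices, "od_matrix")) matrices <- list(matrices)
  mode <- match.arg(mode)
  check_number(k, "k", lower = 1)
  regions <- matrices[[1]]$regions
  if (!affected %in% regions) abort(sprintf("Unknown region '%s'.", affected))
  flows <- if (mode == "destinations") {
    total <- Reduce(`+`, purrr::map(matrices, ~ .x$counts[affected, ]))
    total[setdiff(regions, affected)]
  } else {
    rowSums(Reduce(`+`, purrr::map(matrices, ~ .x$counts)))
  }
  if (k > length(flows)) abort("`k` exceeds the number of eligible regions.")
  ord <- order(-flows, names(flows))
  tibble::tibble(
    rank = seq_len(k),
    region = names(flows)[ord][seq_len(k)],
    flow = unname(flows[ord])[seq_len(k)]
  )
}
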