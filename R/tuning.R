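#' Epsilon tuning table over a grid of accuracy requirements
#'
#' Tabulates, for each error tolerance alpha (and optionally each failure
#' probability delta), the minimal epsilon admitted by the noise-standard-
#' deviation heuristic and by the tail bound. The tail bound always admits
#' a larger epsilon than the heuristic asks for the same alpha when delta
#' is not too small, i.e. a more accurate release for the same accuracy
#' goal.
#'
#' @param alphas Numeric vector of per-cell error tolerances (> 0).
#' @param deltas Numeric vector of failure probabilities in (0, 1\].
#' @param T Contribution bound.
#' @return Tibble with columns `alpha`, `delta`, `T`, `epsilon_heuristic`,
#'   `epsilon_bound`.
#' @examples
#' epsilon_tuning_table(alphas = c(10, 50), deltas = 0.05)
#' @export
epsilon_tuning_table <- function(alphas, deltas = 0.05, T = 1) {
  grid <- tidyr::expand_grid(alpha = alphas, delta = deltas, T = T)
  dplyr::mutate(grid,
    epsilon_heuristic = purrr::map2_dbl(.data$alpha, .data$T,
                                        ~ heuristic_epsilon_for_error(.x, .y)),
    epsilon_bound = purrr::pmap_dbl(
      list(.data$alpha, .data$delta, .data$T),
      ~ epsilon_for_error_bound(..1, ..2, ..3)
    )
  )
}

#' Privacy-accuracy tradeoff plot
#'
#' Plots both epsilon calculators over a range of error tolerances.
#'
#' @param alphas Error tolerances to span.
#' @param delta Failure probability for the tail bound.
#' @param T Contribution bound.
#' @return A ggplot object.
#' @export
plot_epsilon_tradeoff <- function(alphas = seq(2, 100, by = 2), delta = 0.05, T = 1) {
  tab <- epsilon_tuning_table(alphas, delta, T) |>
    tidyr::pivot_longer(dplyr::starts_with("epsilon_"),
                        names_to = "calculator", values_to = "epsilon",
                        names_prefix = "epsilon_")
  ggplot2::ggplot(tab, ggplot2::aes(.data$alpha, .data$epsilon,
                                    colour = .data$calculator)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Per-cell error tolerance α (trips)",
      y = "Minimal admissible ε",
      colour = NULL
    )
}
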