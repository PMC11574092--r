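#' Parameters of the mobility-informed SIR model
#'
#' The metapopulation SIR model couples the classic within-region dynamics
#' with a between-region force of infection weighted by the daily O-D
#' matrix M. For region i with population N_i:
#'
#' \deqn{dS_i/dt = -\beta S_i I_i / N_i
#'   - \alpha \beta S_i \sum_j (M_{ij} I_j / N_j) / (N_i + \sum_j M_{ij})}
#'
#' Recovery is either `"as-printed"` (`dR_i/dt = mu I_i / N_i`, the form
#' accompanying the coupled model) or `"classic"` (`dR_i/dt = mu I_i`, the
#' standard Kermack-McKendrick convention in which mu is the daily fraction
#' of infecteds who recover). The infected compartment absorbs the balance,
#' `dI = -dS - dR`, so each region's S + I + R is conserved exactly.
#'
#' @param beta Intra-region transmission rate per day (default 0.10).
#' @param alpha_mix Inter- vs intra-region mixing ratio (default 1: visitors
#'   mix like residents).
#' @param mu Recovery parameter per day (default 0.04).
#' @param recovery_form `"as-printed"` or `"classic"` (see above).
#' @param step_size Forward-Euler step in days (default 1, the matrix
#'   cadence).
#' @return An object of class `sir_params`.
#' @export
sir_params <- function(beta = 0.10, alpha_mix = 1, mu = 0.04,
                       recovery_form = c("as-printed", "classic"),
                       step_size = 1) {
  check_number(beta, "beta", lower = 0)
  check_number(alpha_mix, "alpha_mix", lower = 0)
  check_number(mu, "mu", lower = 0)
  check_number(step_size, "step_size", lower = 0, strict = TRUE)
  structure(
    list(
      beta = beta, alpha_mix = alpha_mix, mu = mu,
      recovery_form = match.arg(recovery_form), step_size = step_size
    ),
    class = "sir_params"
  )
}

#' One day-step of the mobility-informed SIR model
#'
#' Advances the per-region S/I/R compartments by one forward-Euler step
#' using the day's O-D matrix as the mobility coupling. Suppressed cells of
#' a private matrix enter the force of infection as 0 (their released
#' value). Outflow from S is limited to the available susceptibles, so
#' compartments never go negative and S + I + R = N is preserved exactly.
#'
#' @param state List with numeric vectors `S`, `I`, `R`, `N` (per region,
#'   aligned with `m$regions`) and day index `t`.
#' @param m An [od_matrix] or `private_od_matrix` whose regions match the
#'   state.
#' @param params An [sir_params] object.
#' @return The state one step later (same shape, `t` advanced by
#'   `step_size`).
#' @export
sir_step <- function(state, m, params = sir_params()) {
  stopifnot(inherits(m, "od_matrix"), inherits(params, "sir_params"))
  if (length(state$S) != length(m$regions)) {
    abort("State and O-D matrix have different numbers of regions.")
  }
  if (any(state$N <= 0)) abort("All region populations must be positive.")
  S <- state$S; I <- state$I; R <- state$R; N <- state$N
  M <- m$counts
  h <- params$step_size

  import <- as.vector(M %*% (I / N)) # sum_j M_ij I_j / N_j
  dS <- -params$beta * S * I / N -
    params$alpha_mix * params$beta * S * import / (N + rowSums(M))
  dR <- if (params$recovery_form == "as-printed") params$mu * I / N else params$mu * I
  dS <- pmax(h * dS, -S) # never remove more susceptibles than exist
  dR <- pmin(h * dR, I)
  dI <- -dS - dR

  list(S = S + dS, I = I + dI, R = R + dR, N = N, t = state$t + h)
}

#' Run a mobility-informed SIR epidemic over daily O-D matrices
#'
#' Initializes the epidemic with a fraction `init_frac` of the seed
#' region's population infected (everyone else susceptible, no one
#' recovered) and advances one [sir_step()] per daily matrix, in day
#' order. Prevalence in region i on day t is I_i(t) / N_i.
#'
#' To run the fully private counterpart, pass privatized matrices and a
#' privatized population vector ([privatize_count_vector()]).
#'
#' @param daily_matrices List of [od_matrix] (or `private_od_matrix`)
#'   objects in day order, all over the same regions.
#' @param populations Tibble with columns `region`, `population` (the
#'   time-invariant N_i, >= 1), or a named numeric vector.
#' @param seed_region Region id where the epidemic starts.
#' @param init_frac Initial infected fraction of the seed region's
#'   population (default 0.01).
#' @param params An [sir_params] object.
#' @return An object of class `epidemic_run`; its `series` element is a
#'   tibble with one row per region and day (days `0 .. length(matrices)`)
#'   and columns `day`, `region`, `S`, `I`, `R`, `prevalence`.
#' @export
run_epidemic <- function(daily_matrices, populations, seed_region,
                         init_frac = 0.01, params = sir_params()) {
  if (length(daily_matrices) == 0) abort("Need at least one daily O-D matrix.")
  regions <- daily_matrices[[1]]$regions
  N <- population_vector(populations, regions)
  if (any(N < 1)) abort("All region populations must be >= 1.")
  if (!seed_region %in% regions) {
    abort(sprintf("Unknown seed region '%s'.", seed_region))
  }
  check_number(init_frac, "init_frac", lower = 0)

  I <- setNames(numeric(length(regions)), regions)
  I[seed_region] <- init_frac * N[seed_region]
  state <- list(S = N - I, I = I, R = 0 * N, N = N, t = 0)

  states <- vector("list", length(daily_matrices) + 1)
  states[[1]] <- state
  for (d in seq_along(daily_matrices)) {
    state <- sir_step(state, daily_matrices[[d]], params)
    states[[d + 1]] <- state
  }
  series <- purrr::map_dfr(states, function(s) {
    tibble::tibble(
      day = s$t, region = regions,
      S = unname(s$S), I = unname(s$I), R = unname(s$R),
      prevalence = unname(s$I / s$N)
    )
  })
  structure(
    list(series = series, regions = regions, populations = N,
         seed_region = seed_region, init_frac = init_frac, params = params),
    class = "epidemic_run"
  )
}

population_vector <- function(populations, regions) {
  if (is.data.frame(populations)) {
    v <- setNames(populations$population, populations$region)
  } else {
    v <- populations
  }
  if (!all(regions %in% names(v))) {
    abort("`populations` must cover every region of the matrices.")
  }
  v[regions]
}

#' Threshold-based intervention decisions from a prevalence series
#'
#' A local anti-contagion policy is put in place in a region on a day when
#' its estimated prevalence reaches the threshold (>=, so a region exactly
#' at the threshold intervenes).
#'
#' @param run An `epidemic_run`, or a tibble with columns `day`, `region`,
#'   `prevalence`.
#' @param threshold Prevalence triggering intervention (default 0.20).
#' @return A tibble `day`, `region`, `decision` (0/1).
#' @export
policy_decisions <- function(run, threshold = 0.20) {
  series <- if (inherits(run, "epidemic_run")) run$series else run
  if (any(series$prevalence < 0 | series$prevalence > 1)) {
    abort("Prevalence must lie in [0, 1].")
  }
  dplyr::transmute(series,
    .data$day, .data$region,
    decision = as.integer(.data$prevalence >= threshold)
  )
}

#' @export
print.epidemic_run <- function(x, ...) {
  peak <- dplyr::slice_max(x$series, .data$prevalence, n = 1, with_ties = FALSE)
  cat(sprintf(
    "<epidemic_run> %d regions, %d days, seeded in %s (%.0f%% infected)\n",
    length(x$regions), max(x$series$day), x$seed_region, 100 * x$init_frac
  ))
  cat(sprintf(
    "  peak prevalence %.1f%% in %s on day %d\n",
    100 * peak$prevalence, peak$region, peak$day
  ))
  invisible(x)
}

#' @export
tidy.epidemic_run <- function(x, ...) x$series

#' @export
glance.epidemic_run <- function(x, ...) {
  tibble::tibble(
    n_regions = length(x$regions),
    n_days = max(x$series$day),
    seed_region = x$seed_region,
    peak_prevalence = max(x$series$prevalence),
    final_recovered_frac = sum(x$series$R[x$series$day == max(x$series$day)]) /
      sum(x$populations)
  )
}

#' @export
autoplot.epidemic_run <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(
    object$series,
    ggplot2::aes(.data$day, .data$prevalence, colour = .data$region)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day", y = "Prevalence I/N", colour = "Region")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
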