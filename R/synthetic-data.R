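#' Synthetic mobility scenario
#'
#' Describes a synthetic study population whose statistical structure
#' mirrors CDR-derived mobility data: region populations spanning several
#' orders of magnitude, heavy-tailed per-subscriber trip counts (Poisson
#' daily counts with gamma rate heterogeneity, i.e. negative-binomial
#' marginals), gravity-model destination choice, and an optional shock
#' event that multiplies the out-flow rate from an affected region from a
#' given day onward (an out-migration surge after a disaster).
#'
#' @param k Number of regions (default 34, a province-level setting).
#' @param pop_min,pop_max Range of region populations; drawn log-uniformly
#'   (defaults 1e3 and 1e6).
#' @param n_subscribers Number of synthetic subscribers.
#' @param days Number of days in the window (default 7, a disaster-response
#'   window).
#' @param start_day First calendar day of the window.
#' @param mean_daily_trips Mean per-subscriber inter-region trips per day
#'   (default 0.046, i.e. about 14 trips per subscriber over a 305-day
#'   window).
#' @param trip_dispersion Gamma shape of the subscriber-level rate
#'   heterogeneity; smaller values give a longer upper tail (default 0.3).
#' @param gravity_decay Distance-decay exponent gamma of the gravity
#'   destination kernel N_j / d_ij^gamma (default 1).
#' @param shock `NULL`, or `list(region =, start =, multiplier =)`: from day
#'   index `start` (1-based) onward, subscribers located in `region` have
#'   their trip rate multiplied by `multiplier`.
#' @param seed Integer seed; every random element of the scenario flows
#'   from it.
#' @return An object of class `mobility_scenario`.
#' @examples
#' sc <- mobility_scenario(k = 5, n_subscribers = 200, days = 3, seed = 1)
#' sim <- generate_trips(sc)
#' head(sim$trips)
#' @export
mobility_scenario <- function(k = 34, pop_min = 1e3, pop_max = 1e6,
                              n_subscribers = 2000, days = 7,
                              start_day = as.Date("2020-01-01"),
                              mean_daily_trips = 0.046,
                              trip_dispersion = 0.3,
                              gravity_decay = 1,
                              shock = NULL, seed = 1L) {
  check_number(k, "k", lower = 2)
  check_number(mean_daily_trips, "mean_daily_trips", lower = 0)
  check_number(trip_dispersion, "trip_dispersion", lower = 0, strict = TRUE)
  check_number(gravity_decay, "gravity_decay", lower = 0)
  if (!is.null(shock)) {
    stopifnot(all(c("region", "start", "multiplier") %in% names(shock)))
    if (shock$start < 1 || shock$start > days) {
      abort("Shock start day must fall within the window.")
    }
  }
  structure(
    list(
      k = as.integer(k), pop_min = pop_min, pop_max = pop_max,
      n_subscribers = as.integer(n_subscribers), days = as.integer(days),
      start_day = as.Date(start_day),
      mean_daily_trips = mean_daily_trips,
      trip_dispersion = trip_dispersion,
      gravity_decay = gravity_decay,
      shock = shock, seed = as.integer(seed)
    ),
    class = "mobility_scenario"
  )
}

#' Generate synthetic regions
#'
#' Draws `k` regions with log-uniform populations in `[pop_min, pop_max]`
#' and uniform planar coordinates, from which symmetric pairwise distances
#' are computed.
#'
#' @inheritParams mobility_scenario
#' @param seed Optional integer seed.
#' @return A list with `regions` (ids `R01`, `R02`, ...), `populations`
#'   (tibble `region`, `population`), `coords`, and the `distances`
#'   matrix.
#' @export
generate_regions <- function(k, pop_min = 1e3, pop_max = 1e6, seed = NULL) {
  check_number(k, "k", lower = 2)
  with_seed_opt(seed, {
    regions <- sprintf("R%02d", seq_len(k))
    pops <- round(exp(runif(k, log(pop_min), log(pop_max))))
    coords <- cbind(x = runif(k), y = runif(k))
    d <- as.matrix(stats::dist(coords))
    dimnames(d) <- list(regions, regions)
    list(
      regions = regions,
      populations = tibble::tibble(region = regions, population = pops),
      coords = coords,
      distances = d
    )
  })
}

# Gravity destination kernel: row i gives P(destination = j | origin = i),
# proportional to N_j / d_ij^gamma with the diagonal excluded.
gravity_probs <- function(populations, distances, gamma) {
  k <- nrow(distances)
  W <- outer(rep(1, k), populations) / distances^gamma
  diag(W) <- 0
  W / rowSums(W)
}

#' Generate synthetic trips from a scenario
#'
#' Each subscriber is assigned a home region with probability proportional
#' to population, and a personal daily trip rate drawn from a gamma
#' distribution with mean `mean_daily_trips` (so daily counts are
#' negative-binomial marginally, giving the long upper tail seen in real
#' per-subscriber trip distributions). Subscribers move as a chain: every
#' trip starts at the subscriber's current region and its destination is
#' drawn with probability proportional to N_j / d_ij^gamma. A shock
#' multiplies the trip rate of subscribers located in the affected region
#' from the shock day onward.
#'
#' @param scenario A [mobility_scenario].
#' @return A list of class `mobility_sim`: the scenario, `regions`,
#'   `populations`, `distances`, `homes` (tibble `subscriber_id`,
#'   `home_region`), and `trips` (tibble `subscriber_id`, `day`, `origin`,
#'   `destination`).
#' @export
generate_trips <- function(scenario) {
  stopifnot(inherits(scenario, "mobility_scenario"))
  sc <- scenario
  with_seed_opt(sc$seed, {
    geo <- generate_regions(sc$k, sc$pop_min, sc$pop_max, seed = NULL)
    k <- sc$k
    n <- sc$n_subscribers
    pops <- geo$populations$population
    P <- gravity_probs(pops, geo$distances, sc$gravity_decay)

    subs <- sprintf("S%06d", seq_len(n))
    home_idx <- sample.int(k, n, replace = TRUE, prob = pops)
    rate <- rgamma(n, shape = sc$trip_dispersion,
                   rate = sc$trip_dispersion / max(sc$mean_daily_trips, 1e-12)) *
      (sc$mean_daily_trips > 0)

    loc <- home_idx
    out <- vector("list", sc$days)
    for (d in seq_len(sc$days)) {
      day_rate <- rate
      if (!is.null(sc$shock) && d >= sc$shock$start) {
        hit <- geo$regions[loc] == sc$shock$region
        day_rate[hit] <- day_rate[hit] * sc$shock$multiplier
      }
      n_trips <- rpois(n, day_rate)
      day_list <- list()
      step <- 1L
      while (any(n_trips > 0)) {
        active <- which(n_trips > 0)
        dest <- integer(length(active))
        for (o in unique(loc[active])) {
          sel <- which(loc[active] == o)
          dest[sel] <- sample.int(k, length(sel), replace = TRUE, prob = P[o, ])
        }
        day_list[[step]] <- tibble::tibble(
          subscriber_id = subs[active],
          day = sc$start_day + (d - 1),
          origin = geo$regions[loc[active]],
          destination = geo$regions[dest],
          order = step
        )
        loc[active] <- dest
        n_trips[active] <- n_trips[active] - 1L
        step <- step + 1L
      }
      out[[d]] <- dplyr::bind_rows(day_list)
    }
    empty <- tibble::tibble(
      subscriber_id = character(), day = as.Date(character()),
      origin = character(), destination = character(), order = integer()
    )
    trips <- dplyr::bind_rows(empty, out) |>
      dplyr::arrange(.data$subscriber_id, .data$day, .data$order) |>
      dplyr::select(-"order")
    structure(
      list(
        scenario = sc,
        regions = geo$regions,
        populations = geo$populations,
        distances = geo$distances,
        homes = tibble::tibble(subscriber_id = subs,
                               home_region = geo$regions[home_idx]),
        trips = trips
      ),
      class = "mobility_sim"
    )
  })
}

#' Realize a synthetic simulation as a CDR-style event stream
#'
#' Emits an event stream and tower map consistent with the simulated
#' trips: each subscriber gets one nighttime event at their home region
#' the night before the window (so home inference recovers the assigned
#' homes), followed by one event at the destination of each trip, in
#' order, within the trip's day. Because trips chain (each starts where
#' the previous one ended), extracting trips from these events with
#' [extract_trips()] reproduces the simulated trips exactly.
#'
#' @param sim A `mobility_sim` from [generate_trips()].
#' @return A list with `events` (tibble `subscriber_id`, `timestamp`,
#'   `tower_id`) and `towers` (tibble `tower_id`, `region_id`, one tower
#'   per region).
#' @export
generate_events <- function(sim) {
  stopifnot(inherits(sim, "mobility_sim"))
  towers <- tibble::tibble(
    tower_id = paste0("tw_", sim$regions),
    region_id = sim$regions
  )
  day0 <- sim$scenario$start_day - 1
  home_events <- tibble::tibble(
    subscriber_id = sim$homes$subscriber_id,
    timestamp = as.POSIXct(paste(day0, "02:00:00"), tz = "UTC"),
    tower_id = paste0("tw_", sim$homes$home_region)
  )
  trip_events <- sim$trips |>
    dplyr::group_by(.data$subscriber_id, .data$day) |>
    dplyr::mutate(slot = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$subscriber_id,
      # seconds, not hours: even the heaviest travel day stays inside
      # daytime hours, so trip dates survive the event round-trip
      timestamp = as.POSIXct(paste(.data$day, "08:00:00"), tz = "UTC") +
        (.data$slot - 1),
      tower_id = paste0("tw_", .data$destination)
    )
  list(
    events = dplyr::arrange(
      dplyr::bind_rows(home_events, trip_events),
      .data$subscriber_id, .data$timestamp
    ),
    towers = towers
  )
}

#' @export
print.mobility_scenario <- function(x, ...) {
  cat(sprintf(
    "<mobility_scenario> %d regions, %d subscribers, %d days from %s\n",
    x$k, x$n_subscribers, x$days, format(x$start_day)
  ))
  cat(sprintf(
    "  mean %.3f trips/subscriber/day (dispersion %.2f), gravity decay %.1f%s\n",
    x$mean_daily_trips, x$trip_dispersion, x$gravity_decay,
    if (is.null(x$shock)) "" else
      sprintf("; shock x%g in %s from day %d",
              x$shock$multiplier, x$shock$region, x$shock$start)
  ))
  invisible(x)
}

#' Read and write scenario configuration files
#'
#' Scenarios are stored as YAML so a whole study (generator settings,
#' shock, seed) is one reviewable text file.
#'
#' @param scenario A [mobility_scenario].
#' @param path File path.
#' @return `read_scenario()` returns a `mobility_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "mobility_scenario"))
  x <- unclass(scenario)
  x$start_day <- format(x$start_day)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(mobility_scenario, x)
}
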