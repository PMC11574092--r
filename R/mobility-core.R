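#' Extract inter-region trips from a CDR-style event stream
#'
#' A trip is recorded whenever a subscriber produces an event (call or text)
#' in one administrative region and their next event falls in a different
#' region. Events are sorted by subscriber and timestamp internally, so
#' input order does not matter. Each trip is dated by the day of the later
#' event of the pair (the arrival); with `within_day_only = TRUE`, pairs
#' whose two events fall on different calendar days are skipped.
#'
#' @param events Tibble of events with columns `subscriber_id`,
#'   `timestamp` (POSIXct or ISO-8601 string) and `tower_id`.
#' @param towers Tibble mapping `tower_id` to `region_id`.
#' @param within_day_only If `TRUE`, only consecutive event pairs on the
#'   same calendar day yield trips.
#' @return A tibble of trips with columns `subscriber_id`, `day` (Date),
#'   `origin`, `destination`; origin always differs from destination.
#' @examples
#' events <- tibble::tibble(
#'   subscriber_id = "s1",
#'   timestamp = as.POSIXct("2020-01-01 08:00", tz = "UTC") + c(0, 3600, 7200),
#'   tower_id = c("t1", "t1", "t2")
#' )
#' towers <- tibble::tibble(tower_id = c("t1", "t2"), region_id = c("A", "B"))
#' extract_trips(events, towers)
#' @export
extract_trips <- function(events, towers, within_day_only = FALSE) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      subscriber_id = character(), day = as.Date(character()),
      origin = character(), destination = character()
    ))
  }
  events <- map_events_to_regions(events, towers)
  trips <- events |>
    dplyr::arrange(.data$subscriber_id, .data$timestamp) |>
    dplyr::group_by(.data$subscriber_id) |>
    dplyr::mutate(
      origin = dplyr::lag(.data$region_id),
      prev_day = dplyr::lag(as.Date(.data$timestamp))
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$origin), .data$origin != .data$region_id)
  if (within_day_only) {
    trips <- dplyr::filter(trips, as.Date(.data$timestamp) == .data$prev_day)
  }
  trips |>
    dplyr::transmute(
      .data$subscriber_id,
      day = as.Date(.data$timestamp),
      origin = .data$origin,
      destination = .data$region_id
    )
}

map_events_to_regions <- function(events, towers) {
  events$timestamp <- as.POSIXct(events$timestamp, tz = "UTC")
  idx <- match(events$tower_id, towers$tower_id)
  if (anyNA(idx)) {
    bad <- unique(events$tower_id[is.na(idx)])
    abort(sprintf("Unmapped tower id(s): %s", paste(bad, collapse = ", ")))
  }
  events$region_id <- towers$region_id[idx]
  events
}

#' Build a daily O-D matrix from trips
#'
#' Counts the trips taken on `day` for every ordered region pair over a
#' fixed region index. `build_daily_od_matrices()` does the same for every
#' day in a window, including days with no trips (zero matrices), so the
#' output always has one matrix per day.
#'
#' @param trips Tibble of trips (`subscriber_id`, `day`, `origin`,
#'   `destination`), e.g. from [extract_trips()].
#' @param regions Character vector of region identifiers fixing the matrix
#'   axes; every trip region must appear in it.
#' @param day Calendar day to count (coerced with [as.Date()]).
#' @return An [od_matrix] for `build_od_matrix()`; a list of them (in day
#'   order) for `build_daily_od_matrices()`.
#' @export
build_od_matrix <- function(trips, regions, day) {
  day <- as.Date(day)
  sub <- trips[as.Date(trips$day) == day, , drop = FALSE]
  long <- dplyr::count(sub, .data$origin, .data$destination, name = "count")
  od_matrix_from_long(long, regions = regions, day = day)
}

#' @rdname build_od_matrix
#' @param days Days to build matrices for; defaults to the full range of
#'   days present in `trips`.
#' @export
build_daily_od_matrices <- function(trips, regions, days = NULL) {
  if (is.null(days)) {
    if (nrow(trips) == 0) abort("No trips and no `days` given.")
    r <- range(as.Date(trips$day))
    days <- seq(r[1], r[2], by = "day")
  }
  purrr::map(as.list(as.Date(days)), build_od_matrix, trips = trips, regions = regions)
}

#' Infer home regions and regional populations from nighttime events
#'
#' Each subscriber's home region is the region of the cell tower they used
#' most often during nighttime hours (between 20:00 and 06:00 by default;
#' the window is half-open on both ends). Subscribers with no nighttime
#' events fall back to their modal tower over all hours. Ties are broken by
#' the lexicographically smallest tower id. Regional populations are the
#' number of subscribers whose home is each region.
#'
#' @inheritParams extract_trips
#' @param regions Region identifiers for the population vector; defaults to
#'   the regions present in `towers`.
#' @param night_start,night_end Hour-of-day bounds of the nighttime window
#'   (default 20 and 6, i.e. \[20:00, 24:00) U \[00:00, 06:00)).
#' @return A list with `homes` (tibble `subscriber_id`, `home_region`) and
#'   `populations` (tibble `region`, `population`, one row per region, with
#'   zeros for regions housing no subscriber).
#' @export
infer_home_regions <- function(events, towers, regions = NULL,
                               night_start = 20, night_end = 6) {
  regions <- regions %||% sort(unique(towers$region_id))
  if (nrow(events) == 0) {
    return(list(
      homes = tibble::tibble(subscriber_id = character(), home_region = character()),
      populations = tibble::tibble(region = regions, population = 0)
    ))
  }
  events <- map_events_to_regions(events, towers)
  hr <- as.integer(format(events$timestamp, "%H"))
  events$night <- hr >= night_start | hr < night_end

  modal_tower <- function(df) {
    counts <- sort(table(df$tower_id), decreasing = TRUE)
    # ties: table() orders names lexicographically within equal counts only
    # after an explicit re-sort on (count desc, tower id asc)
    best <- names(counts)[counts == max(counts)]
    min(best)
  }
  homes <- events |>
    dplyr::group_by(.data$subscriber_id) |>
    dplyr::summarise(home_tower = {
      df <- dplyr::pick(dplyr::everything())
      nt <- df[df$night, , drop = FALSE]
      modal_tower(if (nrow(nt) > 0) nt else df)
    }) |>
    dplyr::mutate(
      home_region = towers$region_id[match(.data$home_tower, towers$tower_id)]
    ) |>
    dplyr::select("subscriber_id", "home_region")

  pops <- table(factor(homes$home_region, levels = regions))
  list(
    homes = homes,
    populations = tibble::tibble(
      region = regions,
      population = as.numeric(pops)
    )
  )
}
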