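#' Read and write the mobility CSV dialects
#'
#' Plain CSV dialects shared by every workflow stage:
#' * events: `subscriber_id`, `timestamp` (ISO-8601), `tower_id`
#' * towers: `tower_id`, `region_id`
#' * trips: `subscriber_id`, `day`, `origin`, `destination`
#'
#' @param x Tibble in the corresponding dialect.
#' @param path File path.
#' @return The readers return tibbles; the writers return `path`
#'   invisibly.
#' @name mobility_io
NULL

#' @rdname mobility_io
#' @export
read_events_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(subscriber_id = "c", tower_id = "c"))
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC")
  out
}

#' @rdname mobility_io
#' @export
write_events_csv <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname mobility_io
#' @export
read_towers_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' @rdname mobility_io
#' @export
write_towers_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname mobility_io
#' @export
read_trips_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(subscriber_id = "c",
                                                 origin = "c", destination = "c"))
  out$day <- as.Date(out$day)
  out
}

#' @rdname mobility_io
#' @export
write_trips_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
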