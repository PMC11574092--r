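#' Origin-destination matrix objects
#'
#' An `od_matrix` holds the daily inter-region trip counts for a fixed,
#' ordered set of regions: entry (i, j) is the number of trips observed from
#' region i to region j on one calendar day. Trips are inter-region by
#' definition, so the diagonal is identically zero. A `private_od_matrix`
#' is the differentially private release of an `od_matrix`: it additionally
#' carries a logical suppression grid (cells whose noised value fell below
#' the threshold and are released as 0) and the privacy parameters of the
#' release.
#'
#' @param counts A k x k non-negative integer matrix of trip counts
#'   (diagonal zero). Dimnames, if present, must agree with `regions`.
#' @param regions Character vector of unique region identifiers; its order
#'   fixes the row/column axes.
#' @param day The calendar day of the counts (coerced with [as.Date()]).
#'
#' @return `od_matrix()` returns an object of class `od_matrix`: a list with
#'   elements `day`, `regions` and `counts`.
#' @examples
#' m <- od_matrix(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE),
#'                regions = c("A", "B"), day = "2020-01-01")
#' od_total(m)
#' @export
od_matrix <- function(counts, regions, day) {
  regions <- as.character(regions)
  if (anyDuplicated(regions)) abort("`regions` must be unique.")
  k <- length(regions)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(k, k))) {
    abort(sprintf("`counts` must be %d x %d to match `regions`.", k, k))
  }
  if (any(counts < 0)) abort("O-D counts must be non-negative.")
  if (any(diag(counts) != 0)) {
    abort("O-D matrix diagonal must be zero (trips are inter-region).")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(origin = regions, destination = regions)
  structure(
    list(day = as.Date(day), regions = regions, counts = counts),
    class = "od_matrix"
  )
}

new_private_od_matrix <- function(m, counts, suppressed, params) {
  dimnames(counts) <- dimnames(m$counts)
  dimnames(suppressed) <- dimnames(m$counts)
  structure(
    list(
      day = m$day, regions = m$regions, counts = counts,
      suppressed = suppressed, params = params
    ),
    class = c("private_od_matrix", "od_matrix")
  )
}

#' @rdname od_matrix
#' @param m An `od_matrix`.
#' @export
od_total <- function(m) {
  stopifnot(inherits(m, "od_matrix"))
  sum(m$counts)
}

#' @export
print.od_matrix <- function(x, ...) {
  k <- length(x$regions)
  cat(sprintf(
    "<%s> %s: %d regions, %s trips\n",
    class(x)[1], format(x$day), k, format(sum(x$counts), big.mark = ",")
  ))
  if (inherits(x, "private_od_matrix")) {
    p <- x$params
    cat(sprintf(
      "  epsilon = %g, T = %d, tau = %d; %d/%d off-diagonal cells suppressed\n",
      p$epsilon, p$T, p$tau, sum(x$suppressed), k * (k - 1)
    ))
  }
  invisible(x)
}

#' Long-form view of an O-D matrix
#'
#' Returns one row per ordered region pair with the trip count; for private
#' matrices a `suppressed` flag column is included (suppressed cells carry a
#' released count of 0).
#'
#' @param x An `od_matrix` or `private_od_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `day`, `origin`, `destination`, `count`
#'   (and `suppressed` for private matrices).
#' @method as_tibble od_matrix
#' @export
as_tibble.od_matrix <- function(x, ...) {
  k <- length(x$regions)
  out <- tibble::tibble(
    day = x$day,
    origin = rep(x$regions, times = k),
    destination = rep(x$regions, each = k),
    count = as.vector(x$counts)
  )
  if (inherits(x, "private_od_matrix")) {
    out$suppressed <- as.vector(x$suppressed)
  }
  out
}

#' @export
tidy.od_matrix <- function(x, ...) as_tibble.od_matrix(x)

#' @export
glance.od_matrix <- function(x, ...) {
  tibble::tibble(
    day = x$day,
    n_regions = length(x$regions),
    total_trips = sum(x$counts),
    n_suppressed = if (inherits(x, "private_od_matrix")) sum(x$suppressed) else 0L
  )
}

#' @export
autoplot.od_matrix <- function(object, trans = "log1p", ...) {
  long <- as_tibble.od_matrix(object)
  long$origin <- factor(long$origin, levels = rev(object$regions))
  long$destination <- factor(long$destination, levels = object$regions)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$destination, .data$origin)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::labs(
      x = "Destination", y = "Origin", fill = "Trips",
      title = sprintf("O-D matrix, %s", format(object$day))
    )
  if (inherits(object, "private_od_matrix")) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(long, .data$suppressed),
      shape = 4, size = 1, colour = "grey40"
    )
  }
  p
}

#' Read and write long-form O-D matrix files
#'
#' The on-disk dialect is a long-form CSV with columns `day`, `origin`,
#' `destination`, `count`, plus `suppressed` (0/1) for private matrices.
#' Private matrices additionally write a YAML sidecar
#' (`<path>.meta.yaml`) recording epsilon, T, tau, the seed and an optional
#' admin-level label, and `read_od_csv()` restores it when present.
#'
#' @param matrices An `od_matrix`, `private_od_matrix`, or list of them
#'   (one per day).
#' @param path File path of the CSV.
#' @param admin_level Optional label (e.g. `"admin-2"`) stored in the
#'   sidecar metadata of private releases.
#' @return `read_od_csv()` returns a list of `od_matrix` (or
#'   `private_od_matrix`) objects in day order; `write_od_csv()` returns
#'   `path` invisibly.
#' @export
write_od_csv <- function(matrices, path, admin_level = NULL) {
  if (inherits(matrices, "od_matrix")) matrices <- list(matrices)
  long <- purrr::map_dfr(matrices, as_tibble.od_matrix)
  if ("suppressed" %in% names(long)) {
    long$suppressed <- as.integer(long$suppressed)
  }
  readr::write_csv(long, path)
  if (inherits(matrices[[1]], "private_od_matrix")) {
    p <- matrices[[1]]$params
    meta <- list(
      epsilon = p$epsilon, T = p$T, tau = p$tau,
      seed = p$seed %||% NA, admin_level = admin_level %||% NA
    )
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' @rdname write_od_csv
#' @param regions Region identifiers defining the matrix axes; defaults to
#'   the sorted union of origins and destinations in the file.
#' @export
read_od_csv <- function(path, regions = NULL) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  regions <- regions %||% sort(union(long$origin, long$destination))
  meta_path <- paste0(path, ".meta.yaml")
  params <- if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    privacy_params(
      epsilon = meta$epsilon, T = meta$T, tau = meta$tau,
      seed = if (is.null(meta$seed) || is.na(meta$seed)) NULL else meta$seed
    )
  }
  days <- sort(unique(long$day))
  purrr::map(days, function(d) {
    sub <- long[long$day == d, ]
    m <- od_matrix_from_long(sub, regions = regions, day = d)
    if (!is.null(params) && "suppressed" %in% names(sub)) {
      supp <- matrix(FALSE, length(regions), length(regions))
      idx <- cbind(
        match(sub$origin, regions)[sub$suppressed == 1],
        match(sub$destination, regions)[sub$suppressed == 1]
      )
      supp[idx] <- TRUE
      m <- new_private_od_matrix(m, m$counts, supp, params)
    }
    m
  })
}

# Build an od_matrix from a long tibble (day, origin, destination, count).
od_matrix_from_long <- function(long, regions, day) {
  k <- length(regions)
  counts <- matrix(0, k, k)
  oi <- match(long$origin, regions)
  di <- match(long$destination, regions)
  if (anyNA(oi) || anyNA(di)) {
    bad <- setdiff(union(long$origin, long$destination), regions)
    abort(sprintf("Unknown region(s): %s", paste(bad, collapse = ", ")))
  }
  counts[cbind(oi, di)] <- long$count
  diag(counts) <- 0
  od_matrix(counts, regions, day)
}
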