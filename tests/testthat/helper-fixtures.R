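# Small programmatic fixtures shared across tests.

make_towers <- function(regions = c("A", "B", "C")) {
  tibble::tibble(
    tower_id = paste0("t", seq_along(regions)),
    region_id = regions
  )
}

make_events <- function(subscriber, times, towers, day = "2020-01-01") {
  tibble::tibble(
    subscriber_id = subscriber,
    timestamp = as.POSIXct(paste(day, times), tz = "UTC"),
    tower_id = towers
  )
}

# A fixed 3-region O-D matrix with known counts.
make_od3 <- function(day = "2020-01-01") {
  counts <- matrix(c(
    0, 40, 3,
    25, 0, 18,
    2, 60, 0
  ), nrow = 3, byrow = TRUE)
  od_matrix(counts, regions = c("A", "B", "C"), day = day)
}

random_trips <- function(n, regions, days, seed) {
  withr::with_seed(seed, {
    origin <- sample(regions, n, replace = TRUE)
    dest <- vapply(origin, function(o) sample(setdiff(regions, o), 1), "")
    tibble::tibble(
      subscriber_id = sample(sprintf("s%03d", 1:50), n, replace = TRUE),
      day = sample(as.Date(days), n, replace = TRUE),
      origin = origin,
      destination = unname(dest)
    )
  })
}

# Independent single-population SIR integrator (forward Euler, no
# mobility), used as the oracle for zero-mobility metapopulation runs.
scalar_sir_oracle <- function(S, I, R, N, beta, mu, n_days,
                              recovery = c("as-printed", "classic")) {
  recovery <- match.arg(recovery)
  out <- matrix(NA_real_, n_days + 1, 3, dimnames = list(NULL, c("S", "I", "R")))
  out[1, ] <- c(S, I, R)
  for (t in seq_len(n_days)) {
    dS <- -beta * S * I / N
    dR <- if (recovery == "as-printed") mu * I / N else mu * I
    dS <- max(dS, -S)
    dR <- min(dR, I)
    I <- I - dS - dR
    S <- S + dS
    R <- R + dR
    out[t + 1, ] <- c(S, I, R)
  }
  out
}

zero_matrices <- function(regions, n_days, start = "2020-01-01") {
  k <- length(regions)
  lapply(seq_len(n_days), function(d) {
    od_matrix(matrix(0, k, k), regions, day = as.Date(start) + d - 1)
  })
}

pop_tbl <- function(regions, populations) {
  tibble::tibble(region = regions, population = populations)
}
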