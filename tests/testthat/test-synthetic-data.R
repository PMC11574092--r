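test_that("generated regions respect the population range and are deterministic", {
  geo <- generate_regions(k = 2, pop_min = 1e3, pop_max = 1e6, seed = 1)
  expect_equal(length(geo$regions), 2)
  expect_equal(dim(geo$distances), c(2, 2))
  expect_gt(geo$distances[1, 2], 0)
  expect_equal(geo$distances[1, 2], geo$distances[2, 1])

  geo10 <- generate_regions(k = 10, seed = 2)
  expect_true(all(geo10$populations$population >= 1e3 - 0.5 &
                    geo10$populations$population <= 1e6 + 0.5))
  expect_equal(generate_regions(10, seed = 2), geo10)
  expect_error(generate_regions(1), "k")
})

test_that("generated trips are valid inter-region trips over known regions", {
  sc <- mobility_scenario(k = 6, n_subscribers = 500, days = 5,
                          mean_daily_trips = 0.3, seed = 4)
  sim <- generate_trips(sc)
  expect_true(all(sim$trips$origin != sim$trips$destination))
  expect_true(all(sim$trips$origin %in% sim$regions))
  expect_true(all(sim$trips$destination %in% sim$regions))
  expect_true(all(sim$trips$day >= sc$start_day &
                    sim$trips$day <= sc$start_day + sc$days - 1))
  expect_equal(generate_trips(sc)$trips, sim$trips) # seed determinism
})

test_that("a zero trip rate produces no trips", {
  sc <- mobility_scenario(k = 3, n_subscribers = 50, days = 3,
                          mean_daily_trips = 0, seed = 1)
  expect_equal(nrow(generate_trips(sc)$trips), 0)
})

test_that("realized trip volume matches the configured rate", {
  n <- 10000
  sc <- mobility_scenario(k = 5, n_subscribers = n, days = 5,
                          mean_daily_trips = 0.2, trip_dispersion = 0.5,
                          seed = 8)
  sim <- generate_trips(sc)
  mean_trips <- nrow(sim$trips) / n
  expected <- sc$mean_daily_trips * sc$days
  # negative-binomial total: var per subscriber = m + m^2/shape over the window
  sd_total <- sqrt((expected + expected^2 / sc$trip_dispersion) / n)
  expect_lt(abs(mean_trips - expected), 3 * sd_total)
})

test_that("per-subscriber trip counts are heavy-tailed", {
  sc <- mobility_scenario(k = 5, n_subscribers = 5000, days = 20,
                          mean_daily_trips = 0.1, trip_dispersion = 0.3, seed = 9)
  sim <- generate_trips(sc)
  per_sub <- table(factor(sim$trips$subscriber_id,
                          levels = sprintf("S%06d", 1:5000)))
  q95 <- unname(stats::quantile(per_sub, 0.95))
  expect_equal(unname(stats::quantile(per_sub, 0.05)), 0) # many silent subscribers
  expect_gt(q95 / mean(per_sub), 3) # long upper tail vs the mean
})

test_that("a shock multiplies out-flow from the affected region", {
  # low base rate so the surge does not materially deplete the region's
  # occupancy within the window; the post/pre flow ratio then tracks the
  # configured multiplier up to sampling error and mild depletion
  sc <- mobility_scenario(
    k = 4, n_subscribers = 20000, days = 14, mean_daily_trips = 0.01,
    trip_dispersion = 5, pop_min = 1e4, pop_max = 1e4,
    shock = list(region = "R01", start = 8, multiplier = 5), seed = 10
  )
  sim <- generate_trips(sc)
  days <- seq(sc$start_day, by = "day", length.out = 14)
  ms <- build_daily_od_matrices(sim$trips, sim$regions, days)
  pre <- total_out_migration(ms[1:7], "R01")
  post <- total_out_migration(ms[8:14], "R01")
  ratio <- post / pre
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 6)
})

test_that("the event realization reproduces the simulated trips exactly", {
  sc <- mobility_scenario(k = 5, n_subscribers = 300, days = 4,
                          mean_daily_trips = 0.4, seed = 12)
  sim <- generate_trips(sc)
  ev <- generate_events(sim)
  back <- extract_trips(ev$events, ev$towers)
  sort_trips <- function(x) dplyr::arrange(x, subscriber_id, day, origin, destination)
  expect_equal(sort_trips(back), sort_trips(sim$trips))

  homes <- infer_home_regions(ev$events, ev$towers, regions = sim$regions)
  expect_equal(
    dplyr::arrange(homes$homes, subscriber_id)$home_region,
    dplyr::arrange(sim$homes, subscriber_id)$home_region
  )
})

test_that("scenario configs survive a YAML round trip", {
  sc <- mobility_scenario(k = 7, n_subscribers = 123, days = 9,
                          shock = list(region = "R02", start = 3, multiplier = 4),
                          seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  expect_equal(read_scenario(path), sc)
})

test_that("shock timing outside the window is rejected", {
  expect_error(
    mobility_scenario(days = 7, shock = list(region = "R01", start = 9, multiplier = 2)),
    "window"
  )
})
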