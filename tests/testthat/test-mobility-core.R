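test_that("consecutive events in different regions yield trips", {
  towers <- make_towers()
  events <- make_events("s1", c("08:00", "09:00", "10:00", "11:00"),
                        c("t1", "t1", "t2", "t3"))
  trips <- extract_trips(events, towers)
  expect_equal(trips$origin, c("A", "B"))
  expect_equal(trips$destination, c("B", "C"))
  expect_equal(trips$day, rep(as.Date("2020-01-01"), 2))

  # all events in one region: no trips
  stay <- make_events("s1", c("08:00", "12:00", "18:00"), c("t1", "t1", "t1"))
  expect_equal(nrow(extract_trips(stay, towers)), 0)
})

test_that("cross-midnight pairs are dated by the arrival and gated by within_day_only", {
  towers <- make_towers()
  events <- tibble::tibble(
    subscriber_id = "s1",
    timestamp = as.POSIXct(c("2020-01-01 23:50:00", "2020-01-02 00:10:00"), tz = "UTC"),
    tower_id = c("t1", "t2")
  )
  trips <- extract_trips(events, towers)
  expect_equal(nrow(trips), 1)
  expect_equal(trips$day, as.Date("2020-01-02"))
  expect_equal(nrow(extract_trips(events, towers, within_day_only = TRUE)), 0)
})

test_that("trip extraction is invariant to input ordering and bounded by events - 1", {
  towers <- make_towers()
  events <- dplyr::bind_rows(
    make_events("s1", c("08:00", "09:00", "10:00"), c("t1", "t2", "t1")),
    make_events("s2", c("07:00", "11:00"), c("t3", "t2"))
  )
  shuffled <- events[withr::with_seed(1, sample(nrow(events))), ]
  expect_equal(extract_trips(events, towers), extract_trips(shuffled, towers))

  for (s in unique(events$subscriber_id)) {
    n_ev <- sum(events$subscriber_id == s)
    trips <- extract_trips(events, towers)
    expect_lte(sum(trips$subscriber_id == s), n_ev - 1)
  }
})

test_that("unmapped towers raise an error naming the tower", {
  towers <- make_towers()
  events <- make_events("s1", c("08:00", "09:00"), c("t1", "t99"))
  expect_error(extract_trips(events, towers), "t99")
})

test_that("O-D matrices count trips per ordered pair with zero diagonal", {
  trips <- tibble::tibble(
    subscriber_id = c("s1", "s2", "s3"),
    day = as.Date("2020-01-01"),
    origin = c("A", "A", "B"),
    destination = c("B", "B", "A")
  )
  m <- build_od_matrix(trips, regions = c("A", "B", "C"), day = "2020-01-01")
  expect_equal(m$counts["A", "B"], 2)
  expect_equal(m$counts["B", "A"], 1)
  expect_equal(od_total(m), 3)
  expect_equal(diag(m$counts), setNames(c(0, 0, 0), c("A", "B", "C")))

  empty <- build_od_matrix(trips[0, ], regions = c("A", "B"), day = "2020-01-01")
  expect_equal(od_total(empty), 0)

  bad <- dplyr::mutate(trips, origin = c("A", "Z", "B"))
  expect_error(build_od_matrix(bad, c("A", "B", "C"), "2020-01-01"), "Z")
})

test_that("matrix totals conserve the number of trips", {
  days <- seq(as.Date("2020-01-01"), by = "day", length.out = 4)
  trips <- random_trips(1000, c("A", "B", "C", "D"), days, seed = 42)
  ms <- build_daily_od_matrices(trips, c("A", "B", "C", "D"), days)
  expect_equal(sum(vapply(ms, od_total, 1)), 1000)
})

test_that("home regions come from modal nighttime towers with fallback and tie-break", {
  towers <- make_towers()
  events <- dplyr::bind_rows(
    # s1: nighttime t1, t1; daytime t2 (ignored) -> home A
    make_events("s1", c("21:00", "23:30", "12:00"), c("t1", "t1", "t2")),
    # s2: only daytime events at t2 -> fallback all-hours modal -> B
    make_events("s2", c("10:00", "14:00"), c("t2", "t2")),
    # s3: nighttime tie t1 x2, t2 x2 -> smallest tower id t1 -> A
    make_events("s3", c("20:30", "22:00", "01:00", "05:00"),
                c("t2", "t1", "t2", "t1"))
  )
  res <- infer_home_regions(events, towers)
  homes <- setNames(res$homes$home_region, res$homes$subscriber_id)
  expect_equal(homes[["s1"]], "A")
  expect_equal(homes[["s2"]], "B")
  expect_equal(homes[["s3"]], "A")
  expect_equal(sum(res$populations$population), 3)
  expect_equal(
    res$populations$population[res$populations$region == "A"], 2
  )
})

test_that("the nighttime window is half-open at both ends", {
  towers <- make_towers()
  events <- dplyr::bind_rows(
    # 20:00 is night, 06:00 is not; s1's only night event is at t2
    make_events("s1", c("20:00"), "t2"),
    make_events("s1", c("06:00", "06:30"), c("t1", "t1"))
  )
  res <- infer_home_regions(events, towers)
  expect_equal(res$homes$home_region, "B")
})

test_that("empty event streams give empty homes and zero populations", {
  towers <- make_towers()
  res <- infer_home_regions(make_events(character(), character(), character()), towers)
  expect_equal(nrow(res$homes), 0)
  expect_equal(sum(res$populations$population), 0)
  expect_equal(res$populations$region, c("A", "B", "C"))
})

test_that("population totals equal the number of distinct subscribers", {
  sc <- mobility_scenario(k = 4, n_subscribers = 80, days = 3,
                          mean_daily_trips = 0.4, seed = 11)
  sim <- generate_trips(sc)
  ev <- generate_events(sim)
  res <- infer_home_regions(ev$events, ev$towers, regions = sim$regions)
  expect_equal(sum(res$populations$population),
               length(unique(ev$events$subscriber_id)))
})
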