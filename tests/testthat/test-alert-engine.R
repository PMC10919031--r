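test_that("haversine distance has metric properties and matches two oracles", {
  expect_equal(haversine_km(9.5, 44.2, 9.5, 44.2), 0)
  ## antipodal points: half the great circle
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-9)
  expect_cbs_error(haversine_km(91, 0, 0, 0), "cbs_bad_input")

  skip_if_not_installed("geosphere")
  set.seed(99)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -179, 179)
  lat2 <- lat1 + runif(50, -3, 3); lon2 <- lon1 + runif(50, -3, 3)
  d <- haversine_km(lat1, lon1, lat2, lon2)
  ## symmetric
  expect_equal(d, haversine_km(lat2, lon2, lat1, lon1))
  ## independent formula: spherical law of cosines
  expect_equal(d, law_of_cosines_km(lat1, lon1, lat2, lon2), tolerance = 1e-6)
  ## independent implementation: geosphere, same radius
  dg <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                 r = 6371008.8) / 1000
  expect_equal(d, dg, tolerance = 1e-9)
})

make_signals <- function(times_h, lat, lon, code = "2", t0 = as_utc("2021-03-01")) {
  n <- length(times_h)
  vol <- data.frame(volunteer_id = sprintf("V%02d", 1:n),
                    village_id = sprintf("G%02d", 1:n),
                    phone_token = sprintf("p%02d", 1:n),
                    lat = lat, lon = lon,
                    active_from = t0 - 86400, active_to = t0 + 600 * 3600,
                    stringsAsFactors = FALSE)
  raw <- data.frame(report_id = sprintf("R%02d", 1:n),
                    volunteer_id = vol$volunteer_id,
                    received_at = t0 + times_h * 3600,
                    payload = code, stringsAsFactors = FALSE)
  list(volunteers = vol, reports = parse_reports(raw, dialect_config()))
}

test_that("single-report CCDs emit one event per signal at the signal's time", {
  s <- make_signals(c(1, 2, 3), lat = rep(9.5, 3), lon = rep(44, 3), code = "4")
  ev <- evaluate_stream(s$reports, s$volunteers)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$triggered_at, s$reports$received_at)
  expect_equal(ev$code, rep(4L, 3))
  expect_true(all(ev$verification_status == "pending"))
})

test_that("the ADD cluster rule needs 5 reports within 7 days and 20 km", {
  same_place <- function(times_h) make_signals(times_h, lat = rep(9.5, length(times_h)),
                                               lon = rep(44, length(times_h)))
  ## 5 signals over 2 days in one village: one event, triggered at the 5th
  s <- same_place(c(0, 10, 20, 30, 48))
  ev <- evaluate_stream(s$reports, s$volunteers)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$triggered_at, s$reports$received_at[5])
  expect_equal(sort(strsplit(ev$member_report_ids, ";")[[1]]),
               s$reports$report_id)
  ## threshold not met
  expect_equal(nrow(evaluate_stream(same_place(c(0, 10, 20, 30))$reports,
                                    same_place(c(0, 10, 20, 30))$volunteers)), 0)
  ## 5th report 8 days after the anchor: window exceeded
  late <- same_place(c(0, 10, 20, 30, 8 * 24))
  expect_equal(nrow(evaluate_stream(late$reports, late$volunteers)), 0)
  ## exactly at the closed 168 h bound: still in
  edge <- same_place(c(0, 10, 20, 30, 168))
  expect_equal(nrow(evaluate_stream(edge$reports, edge$volunteers)), 1)
})

test_that("the 20 km radius is measured from the anchor and is decisive", {
  ## one degree of longitude at this latitude, scaled to put the last
  ## signal at a chosen anchor distance
  lat0 <- 9.5; lon0 <- 44
  km_per_deg <- haversine_km(lat0, lon0, lat0, lon0 + 1)
  place_at <- function(km) lon0 + km / km_per_deg
  mk <- function(last_km) make_signals(c(0, 5, 10, 15, 20),
                                       lat = rep(lat0, 5),
                                       lon = c(rep(lon0, 4), place_at(last_km)))
  s25 <- mk(25)
  expect_gt(haversine_km(lat0, lon0, lat0, place_at(25)), 24.9)
  expect_equal(nrow(evaluate_stream(s25$reports, s25$volunteers)), 0)
  s19 <- mk(19)
  expect_equal(nrow(evaluate_stream(s19$reports, s19$volunteers)), 1)
})

test_that("later qualifying signals join the open event instead of seeding a new one", {
  s <- make_signals(c(0, 5, 10, 15, 20, 30, 40, 50, 60, 70),
                    lat = rep(9.5, 10), lon = rep(44, 10))
  ev <- evaluate_stream(s$reports, s$volunteers)
  expect_equal(nrow(ev), 1)
  expect_equal(length(strsplit(ev$member_report_ids, ";")[[1]]), 10)
})

test_that("event evaluation is deterministic and invariant to input row order", {
  s <- random_stream(12, seed = 314)
  ev1 <- evaluate_stream(s$reports, s$volunteers)
  shuffled <- s$reports[sample(nrow(s$reports)), , drop = FALSE]
  ev2 <- evaluate_stream(shuffled, s$volunteers)
  expect_identical(ev1, ev2)
})

test_that("engine equals the exhaustive anchor-greedy oracle on random streams", {
  skip_if_not_installed("geosphere")
  for (seed in 1:300) {
    n <- 4 + (seed %% 9)   # 4..12 signals
    s <- random_stream(n, seed = 5000 + seed,
                       box_deg = c(0.1, 0.3, 0.6)[1 + seed %% 3],
                       span_h = c(100, 200, 400)[1 + seed %% 3])
    got <- canon_events(evaluate_stream(s$reports, s$volunteers))
    want <- oracle_cluster_events(cbind(s$reports,
                                        lat = s$volunteers$lat,
                                        lon = s$volunteers$lon))
    want <- want[order(vapply(want, function(e) paste(e$members, collapse = "|"),
                              character(1)))]
    expect_equal(length(got), length(want), info = paste("seed", seed))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$members, want[[k]]$members, info = paste("seed", seed))
      expect_equal(got[[k]]$trigger, want[[k]]$trigger, info = paste("seed", seed))
    }
  }
})

test_that("every emitted cluster event re-validates its window invariants", {
  for (seed in 1:25) {
    s <- random_stream(12, seed = 9000 + seed, box_deg = 0.3, span_h = 250)
    ev <- evaluate_stream(s$reports, s$volunteers)
    for (i in seq_len(nrow(ev))) {
      mem <- strsplit(ev$member_report_ids[i], ";")[[1]]
      idx <- match(mem, s$reports$report_id)
      dt <- as.numeric(difftime(s$reports$received_at[idx],
                                min(s$reports$received_at[idx]), units = "hours"))
      expect_true(all(dt <= 168))
      vl <- match(s$reports$volunteer_id[idx], s$volunteers$volunteer_id)
      d <- haversine_km(ev$anchor_lat[i], ev$anchor_lon[i],
                        s$volunteers$lat[vl], s$volunteers$lon[vl])
      expect_true(all(d <= 20))
      expect_gte(length(mem), 5)
    }
  }
})

test_that("signals with no active CCD at their timestamp are rejected", {
  cfg <- ccd_config(
    ccd_definition(2L, "ADD", threshold_count = 5L, window_hours = 168,
                   radius_km = 20),
    ccd_definition(9L, "resp", valid_from = "2021-07-01")
  )
  s <- make_signals(2, lat = 9.5, lon = 44, code = "9")  # March: not yet valid
  expect_cbs_error(evaluate_stream(s$reports, s$volunteers, cfg),
                   "cbs_unconfigured_code")
  ## after the validity start it is accepted
  s2 <- make_signals(2, lat = 9.5, lon = 44, code = "9",
                     t0 = as_utc("2021-08-01"))
  expect_equal(nrow(evaluate_stream(s2$reports, s2$volunteers, cfg)), 1)
})

test_that("a revised cluster definition applies by signal timestamp", {
  cfg <- ccd_config(
    ccd_definition(2L, "ADD v1", threshold_count = 5L, window_hours = 168,
                   radius_km = 20, valid_to = "2021-06-01"),
    ccd_definition(2L, "ADD v2", threshold_count = 3L, window_hours = 168,
                   radius_km = 20, valid_from = "2021-06-01")
  )
  ## three co-located signals: not enough under v1, enough under v2
  s_old <- make_signals(c(0, 5, 10), lat = rep(9.5, 3), lon = rep(44, 3))
  expect_equal(nrow(evaluate_stream(s_old$reports, s_old$volunteers, cfg)), 0)
  s_new <- make_signals(c(0, 5, 10), lat = rep(9.5, 3), lon = rep(44, 3),
                        t0 = as_utc("2021-07-01"))
  expect_equal(nrow(evaluate_stream(s_new$reports, s_new$volunteers, cfg)), 1)
})

test_that("pending notifications flag the 12 h verification breach", {
  led <- mini_ledger()
  t0 <- led$events$triggered_at[1]
  pn3 <- pending_notifications(led$events, t0 + 3 * 3600)
  expect_false(pn3$breached[1])
  pn13 <- pending_notifications(led$events, t0 + 13 * 3600)
  expect_true(pn13$breached[1])
  ## verified events are not listed
  led2 <- verify_event(led, led$events$event_id[1], "kept", t0 + 3600)
  pn <- pending_notifications(led2$events, t0 + 13 * 3600)
  expect_false(led2$events$event_id[1] %in% pn$event_id)
  expect_equal(nrow(pn), nrow(led$events) - 1)
})
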