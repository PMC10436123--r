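times10 <- t_at("12:00:00") + (0:9) * 360

test_that("provider filter keeps exactly the active-provider fixes", {
  tr <- make_trace(times10, lat = 37.7, lon = -122.4,
                   provider = c("gps", "network-passive", "fused",
                                "network-passive", "gps", "gps-passive",
                                "gps", "fused", "network-passive", "gps"))
  out <- filter_by_provider(tr)
  expect_equal(nrow(out), 6)
  expect_true(all(!out$provider %in% c("network-passive", "gps-passive")))
  # all-passive trace legally empties
  expect_equal(nrow(filter_by_provider(make_trace(times10, 37.7, -122.4,
                                                  provider = "gps-passive"))), 0)
})

test_that("provider filter matches a brute-force oracle, idempotently, keeping order", {
  set.seed(11)
  provs <- c("gps", "fused", "network-passive", "gps-passive")
  for (i in 1:100) {
    n <- sample(1:30, 1)
    tr <- make_trace(t_at("00:00:00") + sort(sample(1e5, n)),
                     lat = runif(n, 37, 38), lon = runif(n, -123, -122),
                     provider = sample(provs, n, replace = TRUE))
    keep <- vapply(seq_len(n), function(j)
      !(tr$provider[j] %in% c("network-passive", "gps-passive")), logical(1))
    oracle <- tr[keep, ]; rownames(oracle) <- NULL
    got <- filter_by_provider(tr)
    expect_identical(got, oracle)
    expect_identical(filter_by_provider(got), got)   # idempotent
    expect_true(!is.unsorted(got$timestamp))          # order preserved
  }
})

test_that("home is the modal nighttime bin with earliest-first tie-breaking", {
  # all night fixes identical -> exact coordinate with full support
  night <- t_at("23:00:00") + (0:4) * 360
  tr <- make_trace(night, lat = 37.75123, lon = -122.41234)
  h <- detect_home(tr, tz = STUDY_TZ)
  expect_equal(h$latitude, 37.75123)
  expect_equal(h$longitude, -122.41234)
  expect_equal(h$support, 5L)

  # two bins, equal counts: the bin seen first wins
  tr2 <- make_trace(t_at("22:00:00") + (0:3) * 600,
                    lat = c(37.8000, 37.9000, 37.8001, 37.9001),
                    lon = -122.4)
  h2 <- detect_home(tr2, bin_precision = 3, tz = STUDY_TZ)
  expect_equal(round(h2$latitude, 3), 37.8)
  expect_equal(h2$support, 2L)

  # daytime-only fixes: distinct "home undetectable" error
  day <- make_trace(t_at("12:00:00") + (0:4) * 360, 37.7, -122.4)
  expect_error(detect_home(day, tz = STUDY_TZ), "home undetectable")
  expect_error(detect_home(day[0, ], tz = STUDY_TZ), "empty trace")
})

test_that("home detection is order-invariant up to the tie rule", {
  set.seed(5)
  n <- 40
  tr <- make_trace(t_at("21:30:00") + (0:(n - 1)) * 360,
                   lat = 37.75 + rnorm(n, 0, 1e-4),
                   lon = -122.41 + rnorm(n, 0, 1e-4))
  h1 <- detect_home(tr, tz = STUDY_TZ)
  perm <- sample(n)
  tr2 <- tr[perm, ]
  tr2$timestamp <- sort(tr2$timestamp)   # keep contract, permute coordinates
  h2 <- detect_home(tr2, tz = STUDY_TZ)
  expect_equal(h2$latitude, h1$latitude)
  expect_equal(h2$longitude, h1$longitude)
})

test_that("home removal is radius-based with haversine distances", {
  home <- structure(list(latitude = 37.75, longitude = -122.41),
                    class = "home_location")
  # a point 40 m north of home: removed at radius 50, kept at radius 30
  lat40 <- 37.75 + 40 / 111319.49
  tr <- make_trace(times10[1:3], lat = c(37.75, lat40, 37.76),
                   lon = -122.41)
  expect_equal(nrow(remove_home_points(tr, home, radius = 50)), 1)
  expect_equal(nrow(remove_home_points(tr, home, radius = 30)), 2)
  # radius 0 removes only exact coordinate matches
  r0 <- remove_home_points(tr, home, radius = 0)
  expect_equal(r0$lat, c(lat40, 37.76))
  # trace entirely at home empties gracefully; removal is idempotent
  allhome <- make_trace(times10, 37.75, -122.41)
  gone <- remove_home_points(allhome, home, 10)
  expect_equal(nrow(gone), 0)
  expect_equal(nrow(remove_home_points(gone, home, 10)), 0)
  expect_error(remove_home_points(tr, home, -5), "nonnegative")
})

test_that("travel days are flagged per day, participants on full travel excluded", {
  region <- c(xmin = -123, xmax = -122, ymin = 37, ymax = 38)
  day1 <- t_at("10:00:00") + (0:3) * 3600
  day3 <- t_at("10:00:00", "2023-05-03") + (0:3) * 3600
  tr <- make_trace(c(day1, day3), lat = 37.5, lon = -122.5)
  expect_equal(nrow(flag_travel_days(tr, region, STUDY_TZ)$days), 0)

  tr$lon[6] <- -80   # one fix outside on day 3
  fl <- flag_travel_days(tr, region, STUDY_TZ)
  expect_equal(fl$days$date, as.Date("2023-05-03"))
  expect_false(fl$participant_excluded)

  traveler <- make_trace(c(day1, day3), lat = 40.7, lon = -74)
  expect_true(flag_travel_days(traveler, region, STUDY_TZ)$participant_excluded)
})

test_that("time at home converts home-fix counts to hours per day", {
  home <- structure(list(latitude = 37.75, longitude = -122.41),
                    class = "home_location")
  day <- t_at("00:00:00") + (0:239) * 360          # 240 fixes, 6-min epochs
  allhome <- make_trace(day, 37.75, -122.41)
  th <- compute_time_at_home(allhome, home, radius = 100, epoch = 6,
                             tz = STUDY_TZ)
  expect_equal(th$hours_at_home, 24)
  half <- allhome
  half$lat[1:120] <- 38.2                           # half the fixes far away
  expect_equal(compute_time_at_home(half, home, 100, 6,
                                    STUDY_TZ)$hours_at_home, 12)
  expect_error(compute_time_at_home(allhome, home, 100, 0, STUDY_TZ),
               "positive")
})

test_that("preprocessing chain reports stage counts and detected home", {
  set.seed(9)
  cfg <- quick_cfg(seed = 9)
  coh <- generate_cohort(cfg)
  tr <- coh$traces[coh$traces$participant_id == "ssd01", ]
  pp <- preprocess_trace(tr, raster_extent(coh$raster), tz = cfg$tz)
  expect_lt(pp$report$n_after_provider_filter, pp$report$n_input)
  expect_lt(pp$report$n_after_home_removal, pp$report$n_after_provider_filter)
  truth <- coh$truth$homes[coh$truth$homes$participant_id == "ssd01", ]
  d <- geosphere::distHaversine(c(pp$home$longitude, pp$home$latitude),
                                c(truth$home_lon, truth$home_lat))
  expect_lt(d, 150)
  expect_false(pp$travel$participant_excluded)
})
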