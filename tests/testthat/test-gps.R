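test_that("haversine distance has the expected geometry", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(10, 20, -5, 140), haversine_km(-5, 140, 10, 20))
  # one degree of longitude at the equator: 2*pi*6371/360
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 1e-6)
})

test_that("speed filter removes implausible fixes and is idempotent", {
  tt <- as.POSIXct("2014-12-05 00:00:00", tz = "UTC") + seq(0, 1200, by = 120)
  lat <- rep(-38, 11)
  lon <- seq(144, 144.1, length.out = 11)       # ~26 km/h legs
  fx <- data.frame(time = tt, lat = lat, lon = lon)
  expect_equal(nrow(speed_filter(fx, vmax = 85)), 11)  # identity below vmax

  fx_bad <- fx
  fx_bad$lat[5] <- -36                            # ~ thousands of km/h spike
  out <- speed_filter(fx_bad, vmax = 85)
  expect_equal(nrow(out), 10)
  expect_false(-36 %in% out$lat)
  expect_equal(speed_filter(out, vmax = 85), out)  # idempotent

  # filtering never increases total track length
  len <- function(f) sum(haversine_km(f$lat[-nrow(f)], f$lon[-nrow(f)],
                                      f$lat[-1], f$lon[-1]))
  expect_lte(len(out), len(fx_bad))
})

test_that("trip segmentation measures out-and-back excursions", {
  colony <- c(-38.2783, 144.6967)
  t0 <- as.POSIXct("2014-12-05 00:00:00", tz = "UTC")
  # stay near the colony: no trips
  near <- data.frame(time = t0 + seq(0, 600, 120),
                     lat = colony[1] + 1e-4, lon = colony[2])
  ts0 <- segment_trips(near, colony)
  expect_equal(ts0$n_trips, 0L)
  expect_equal(ts0$total_distance_km, 0)

  # straight out-and-back with ~50 km legs along a meridian
  leg <- seq(0, 50 / 111.19494, length.out = 26)
  lat <- colony[1] + c(leg, rev(leg)[-1])
  fx <- data.frame(time = t0 + seq_along(lat) * 120, lat = lat, lon = colony[2])
  ts <- segment_trips(fx, colony)
  expect_equal(ts$n_trips, 1L)
  expect_equal(ts$total_distance_km, 100, tolerance = 0.02)
  # trips never overlap in time
  if (ts$n_trips > 1)
    expect_true(all(ts$trips$start[-1] >= ts$trips$end[-ts$n_trips]))

  # inserting a collinear midpoint leaves distance unchanged within 0.1%
  mid <- data.frame(time = fx$time[1] + 60,
                    lat = (lat[1] + lat[2]) / 2, lon = colony[2])
  fx2 <- rbind(fx[1, ], mid, fx[-1, ])
  ts2 <- segment_trips(fx2, colony)
  expect_lt(abs(ts2$total_distance_km / ts$total_distance_km - 1), 0.001)

  # clipping to a window truncates accounting
  ts3 <- segment_trips(fx, colony, window = c(t0, fx$time[10]))
  expect_lt(ts3$total_distance_km, ts$total_distance_km)
})

test_that("sunrise and sunset match an independent solar oracle", {
  lat <- -38.2783; lon <- 144.6967
  for (d in c("2014-12-06", "2014-06-21", "2015-03-20")) {
    st <- sun_times(as.Date(d), lat, lon)
    or <- spencer_sun(as.Date(d), lat, lon)
    expect_lt(abs(as.numeric(difftime(st$sunrise, or$sunrise, units = "mins"))), 2)
    expect_lt(abs(as.numeric(difftime(st$sunset, or$sunset, units = "mins"))), 2)
  }
  expect_error(sun_times(as.Date("2014-12-21"), -85, 0), "polar")
})

test_that("day/night apportionment conserves the interval", {
  lat <- -38.2783; lon <- 144.6967
  st <- sun_times(as.Date("2014-12-06"), lat, lon)
  # interval fully inside daylight
  mid <- st$sunrise + as.numeric(difftime(st$sunset, st$sunrise, units = "secs")) / 2
  out <- day_night_split(st$sunrise + 3600, mid, lat, lon)
  expect_equal(out$T_night_h, 0, tolerance = 1e-9)

  # conservation over a multi-day interval
  a <- as.POSIXct("2014-12-04 13:00:00", tz = "UTC")
  b <- a + 3.2 * 86400
  out2 <- day_night_split(a, b, lat, lon)
  expect_equal(out2$T_day_h + out2$T_night_h, 3.2 * 24)
  expect_gt(out2$T_day_h, out2$T_night_h)  # austral summer

  # per-second daylight flag agrees with the interval split
  secs <- seq(a, b, by = 3600)
  frac_day <- mean(is_daytime(secs, lat, lon))
  expect_equal(frac_day, out2$T_day_h / (3.2 * 24), tolerance = 0.02)
})
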