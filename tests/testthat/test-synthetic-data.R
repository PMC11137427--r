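test_that("generator handles the empty case and rejects bad configs", {
  expect_equal(nrow(generate_sessions(generator_config(n_sessions = 0))), 0)

  expect_error(generator_config(region_shares = c(
    Midwest = 0.5, Northeast = 0.5, Southeast = 0.5, Southwest = 0.5,
    West = 0.5
  )), "region_shares")
  expect_error(generator_config(short_duration_share = 1.2),
               "short_duration_share")
  expect_error(generator_config(detour_factor_mean = 0.9),
               "detour_factor_mean")
  expect_error(generator_config(peak_hour_share = -0.1), "peak_hour_share")
})

test_that("two runs with the same config and seed are identical", {
  cfg <- generator_config(n_sessions = 2000, seed = 77)
  expect_identical(generate_sessions(cfg), generate_sessions(cfg))
  # and a different seed actually changes the draws
  cfg2 <- generator_config(n_sessions = 2000, seed = 78)
  expect_false(identical(generate_sessions(cfg), generate_sessions(cfg2)))
})

test_that("generated population recovers the configured structure at n=100,000", {
  cfg <- generator_config(n_sessions = 100000, seed = 20240515)
  s <- generate_sessions(cfg)
  expect_equal(nrow(s), 100000)

  # regional shares within +/- 0.5 percentage points of the configured
  # (observed-platform) shares, computed over records with a known region
  shares <- prop.table(table(s$region))
  target <- c(Midwest = 0.1726, Northeast = 0.3418, Southeast = 0.2042,
              Southwest = 0.0915, West = 0.1899)
  expect_true(all(abs(shares[names(target)] - target) < 0.005))

  # all in-rule durations lie in [5, 120]; short/long split within 1 point
  valid <- s$duration_min >= 5 & s$duration_min <= 120
  expect_true(all(s$duration_min[valid] >= 5 & s$duration_min[valid] <= 120))
  expect_lt(abs(mean(s$duration_min[valid] <= 30) - 0.4406), 0.01)

  # per-region one-way geodesic medians within 10% of the calibration
  # targets (half the observed round-trip road medians)
  g <- haversine_miles(s$provider_lat, s$provider_lon,
                       s$patient_lat, s$patient_lon)
  targets <- c(Midwest = 24, Northeast = 23, Southeast = 31.5,
               Southwest = 24.5, West = 22)
  med <- tapply(g, s$region, median)
  expect_true(all(abs(med[names(targets)] / targets - 1) < 0.10))

  # weekday concentration and peak-hour share carried into timestamps
  wd <- as.integer(format(s$start_utc, "%u", tz = "UTC"))
  expect_lt(abs(mean(wd <= 5) - (1 - 2479 / 79904)), 0.01)
  hr <- as.integer(format(s$start_utc, "%H", tz = "UTC"))
  expect_lt(abs(mean(hr >= 13) - 0.85), 0.01)

  # planted violations exist at roughly the configured rate
  n_bad <- sum(s$duration_min < 5 | s$duration_min > 120 |
                 s$n_participants > 2 | is.na(s$region))
  expect_equal(n_bad, floor(0.02 * 100000), tolerance = 0.01)
})

test_that("synthetic router is deterministic and never undercuts geodesic", {
  r <- synthetic_router(detour_factor_mean = 1.3, detour_factor_sd = 0.1,
                        speed_mph = 45, seed = 5)

  # zero distance
  expect_equal(route(r, 40, -75, 40, -75),
               tibble::tibble(road_miles = 0, travel_hours = 0))

  # degenerate distribution: sd = 0 gives exactly geodesic x mean
  r0 <- synthetic_router(detour_factor_mean = 1.3, detour_factor_sd = 0,
                         seed = 5)
  p <- teleco2:::destination_point(40, -75, 0.7, 10)
  expect_equal(route(r0, 40, -75, p$lat, p$lon)$road_miles, 13,
               tolerance = 1e-9)

  # property: road >= geodesic over random point pairs; time proportional
  pairs <- random_point_pairs(500, seed = 31)
  g <- haversine_miles(pairs$lat1, pairs$lon1, pairs$lat2, pairs$lon2)
  out <- route(r, pairs$lat1, pairs$lon1, pairs$lat2, pairs$lon2)
  expect_true(all(out$road_miles >= g - 1e-9))
  expect_equal(out$travel_hours, out$road_miles / 45, tolerance = 1e-12)

  # identical query, any order: identical answer
  out2 <- route(r, pairs$lat1[c(2, 1)], pairs$lon1[c(2, 1)],
                pairs$lat2[c(2, 1)], pairs$lon2[c(2, 1)])
  expect_equal(out2$road_miles, out$road_miles[c(2, 1)])

  expect_error(route(r, 95, 0, 0, 0), "invalid coordinate")
  expect_error(synthetic_router(detour_factor_mean = 0.8), ">= 1")
})
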