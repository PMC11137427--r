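test_that("haversine matches closed-form arc lengths on the package sphere", {
  # coincident points
  expect_equal(haversine_miles(40, -75, 40, -75), 0)
  # one degree of latitude = 1/360 of the circumference
  expect_equal(haversine_miles(0, 0, 1, 0), 2 * pi * 3958.8 / 360,
               tolerance = 1e-12)
  # antipodal points on the equator = half circumference
  expect_equal(haversine_miles(0, 0, 0, 180), pi * 3958.8, tolerance = 1e-12)
  # symmetry
  expect_equal(haversine_miles(12.3, -45.6, 48.9, 7.1),
               haversine_miles(48.9, 7.1, 12.3, -45.6))
})

test_that("haversine agrees with a brute-force great-circle integration", {
  pairs <- random_point_pairs(100, seed = 42)
  h <- haversine_miles(pairs$lat1, pairs$lon1, pairs$lat2, pairs$lon2)
  oracle <- mapply(brute_force_gc_miles,
                   pairs$lat1, pairs$lon1, pairs$lat2, pairs$lon2)
  expect_true(all(abs(h - oracle) / oracle < 1e-6))
})

test_that("haversine agrees with geosphere on the same sphere", {
  skip_if_not_installed("geosphere")
  pairs <- random_point_pairs(50, seed = 7)
  h <- haversine_miles(pairs$lat1, pairs$lon1, pairs$lat2, pairs$lon2)
  ref <- geosphere::distHaversine(cbind(pairs$lon1, pairs$lat1),
                                  cbind(pairs$lon2, pairs$lat2), r = 3958.8)
  expect_equal(h, ref, tolerance = 1e-9)
})

test_that("invalid coordinates raise a domain error", {
  expect_error(haversine_miles(95, 0, 0, 0), "invalid coordinate")
  expect_error(haversine_miles(0, 0, 0, 181), "invalid coordinate")
})

test_that("destination_point places patients at the sampled distance", {
  set.seed(11)
  lat <- runif(200, -60, 60)
  lon <- runif(200, -150, 150)
  bearing <- runif(200, 0, 2 * pi)
  dist <- exp(runif(200, log(0.5), log(400)))
  p <- teleco2:::destination_point(lat, lon, bearing, dist)
  expect_equal(haversine_miles(lat, lon, p$lat, p$lon), dist,
               tolerance = 1e-9)
})

test_that("estimate_travel populates a consistent travel record", {
  r_unit <- synthetic_router(detour_factor_mean = 1, detour_factor_sd = 0,
                             speed_mph = 45, seed = 1)

  # coincident coordinates: every field zero
  s0 <- make_sessions(1, patient_lat = 40.0, patient_lon = -75.0)
  t0 <- estimate_travel(s0, r_unit)
  expect_equal(t0$geodesic_miles, 0)
  expect_equal(t0$round_trip_miles, 0)
  expect_equal(t0$round_trip_hours, 0)
  expect_equal(t0$adjusted_round_trip_miles, 0)

  # unit detour: round trip is exactly twice the geodesic; 24.525 -> 49.05
  p <- teleco2:::destination_point(40, -75, 1.1, 24.525)
  s1 <- make_sessions(1, patient_lat = p$lat, patient_lon = p$lon)
  t1 <- estimate_travel(s1, r_unit)
  expect_equal(t1$round_trip_miles, 49.05, tolerance = 1e-9)

  # mode-share scaling: 100 round-trip miles at 0.848 -> 84.8 adjusted
  p2 <- teleco2:::destination_point(40, -75, 0.3, 50)
  s2 <- make_sessions(1, patient_lat = p2$lat, patient_lon = p2$lon)
  t2 <- estimate_travel(s2, r_unit, car_share = 0.848)
  expect_equal(t2$round_trip_miles, 100, tolerance = 1e-9)
  expect_equal(t2$adjusted_round_trip_miles, 84.8, tolerance = 1e-9)

  # car_share = 1 makes adjusted == round trip
  t3 <- estimate_travel(s2, r_unit, car_share = 1)
  expect_equal(t3$adjusted_round_trip_miles, t3$round_trip_miles)
})

test_that("travel fields satisfy the router contract and scale linearly", {
  s <- generate_sessions(generator_config(n_sessions = 400, seed = 21))
  tr <- estimate_travel(s, synthetic_router(seed = 21))
  expect_true(all(tr$oneway_road_miles >= tr$geodesic_miles - 1e-9))
  expect_equal(tr$round_trip_miles, 2 * tr$oneway_road_miles)
  expect_true(all(tr$adjusted_round_trip_miles <= tr$round_trip_miles + 1e-12))
  # time strictly proportional to distance at fixed speed
  expect_equal(tr$round_trip_hours, tr$round_trip_miles / 45, tolerance = 1e-12)

  # doubling one-way road distance doubles round trip, adjusted and time
  doubled <- tr
  doubled$oneway_road_miles <- 2 * tr$oneway_road_miles
  expect_equal(2 * tr$round_trip_miles / 45, 2 * tr$round_trip_hours,
               tolerance = 1e-12)
})
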