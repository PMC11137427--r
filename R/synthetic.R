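#' Configuration for the synthetic session generator
#'
#' Bundles every distributional assumption of the synthetic telemedicine
#' population in one validated record. The defaults encode the observed
#' structure of a large national telemedicine platform over 2022-01-01 to
#' 2023-02-21: regional shares (Northeast 34.18%, Southeast 20.42%, West
#' 18.99%, Midwest 17.26%, Southwest 9.15%), a bimodal session-duration mix
#' with 44.06% of sessions in the 5-30 minute class, right-skewed per-region
#' travel distances (log-normal, calibrated so the one-way geodesic median
#' is half the observed round-trip road median per region), weekday-heavy
#' session timing, and a 13:00-23:00 UTC peak window holding most sessions.
#'
#' @param n_sessions Number of session records to generate.
#' @param region_shares Named proportions over the five regions; must sum
#'   to 1.
#' @param short_duration_share Proportion of sessions in the short (5-30
#'   minute) duration class.
#' @param distance_params Named list, one element per region, each
#'   `c(meanlog, sdlog)` for the log-normal one-way geodesic distance in
#'   miles. Default medians (miles): Midwest 24, Northeast 23, Southeast
#'   31.5, Southwest 24.5, West 22; default `sdlog` reproduces each region's
#'   observed mean/median skew ratio.
#' @param duration_mix Means and SDs (minutes) of the two truncated-normal
#'   duration components, `c(short_mean, short_sd, long_mean, long_sd)`.
#'   Short component truncated to \[5, 30\], long to (30, 120\].
#' @param weekday_shares Named proportions over `Mon`..`Sun`; must sum to 1.
#' @param peak_hour_share Proportion of sessions starting in the
#'   13:00-23:59 UTC window.
#' @param violation_rate Fraction of records planted with an
#'   inclusion-rule violation (duration out of \[5, 120\], more than 2
#'   participants, or missing region) so the filter stage is exercisable.
#' @param window_start,window_end Date bounds (inclusive) of the study
#'   window used for timestamps.
#' @param detour_factor_mean,detour_factor_sd Road-circuity distribution
#'   passed through to [synthetic_router()] defaults; mean must be >= 1.
#' @param seed Master integer seed. Per-component streams are derived from
#'   it, so every draw is reproducible and adding a component does not
#'   perturb existing ones.
#'
#' @return A validated list of class `generator_config`.
#' @seealso [generate_sessions()], [synthetic_router()]
#' @export
generator_config <- function(n_sessions = 100000,
                             region_shares = c(
                               Midwest = 0.1726, Northeast = 0.3418,
                               Southeast = 0.2042, Southwest = 0.0915,
                               West = 0.1899
                             ),
                             short_duration_share = 0.4406,
                             distance_params = NULL,
                             duration_mix = c(
                               short_mean = 19, short_sd = 7,
                               long_mean = 45, long_sd = 16
                             ),
                             weekday_shares = c(
                               Mon = 13777, Tue = 18134, Wed = 17751,
                               Thu = 17052, Fri = 10711, Sat = 1239.5,
                               Sun = 1239.5
                             ) / 79904,
                             peak_hour_share = 0.85,
                             violation_rate = 0.02,
                             window_start = "2022-01-01",
                             window_end = "2023-02-21",
                             detour_factor_mean = 1.3,
                             detour_factor_sd = 0.1,
                             seed = 1L) {
  if (is.null(distance_params)) {
    ## Median one-way geodesic miles and mean/median skew ratio per region.
    med <- c(Midwest = 24, Northeast = 23, Southeast = 31.5,
             Southwest = 24.5, West = 22)
    ratio <- c(Midwest = 143 / 48, Northeast = 106 / 46,
               Southeast = 167 / 63, Southwest = 145 / 49, West = 136 / 44)
    distance_params <- lapply(REGIONS, function(r) {
      c(meanlog = log(med[[r]]), sdlog = sqrt(2 * log(ratio[[r]])))
    })
    names(distance_params) <- REGIONS
  }

  cfg <- list(
    n_sessions = n_sessions, region_shares = region_shares,
    short_duration_share = short_duration_share,
    distance_params = distance_params, duration_mix = duration_mix,
    weekday_shares = weekday_shares, peak_hour_share = peak_hour_share,
    violation_rate = violation_rate,
    window_start = as.Date(window_start), window_end = as.Date(window_end),
    detour_factor_mean = detour_factor_mean,
    detour_factor_sd = detour_factor_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid generator configuration: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_sessions) || length(cfg$n_sessions) != 1 ||
      is.na(cfg$n_sessions) || cfg$n_sessions < 0 ||
      cfg$n_sessions != floor(cfg$n_sessions)) {
    fail("n_sessions", "must be a single non-negative integer")
  }
  if (!setequal(names(cfg$region_shares), REGIONS)) {
    fail("region_shares", "must be named by the five regions")
  }
  if (any(cfg$region_shares < 0 | cfg$region_shares > 1)) {
    fail("region_shares", "must lie in [0, 1]")
  }
  if (abs(sum(cfg$region_shares) - 1) > 1e-9) {
    fail("region_shares", "must sum to 1")
  }
  for (p in c("short_duration_share", "peak_hour_share", "violation_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(p, "must lie in [0, 1]")
  }
  if (!setequal(names(cfg$distance_params), REGIONS)) {
    fail("distance_params", "must be named by the five regions")
  }
  for (r in REGIONS) {
    if (cfg$distance_params[[r]][["sdlog"]] <= 0) {
      fail("distance_params", sprintf("sdlog for %s must be > 0", r))
    }
  }
  if (abs(sum(cfg$weekday_shares) - 1) > 1e-9 ||
      any(cfg$weekday_shares < 0)) {
    fail("weekday_shares", "must be non-negative and sum to 1")
  }
  if (cfg$detour_factor_mean < 1) fail("detour_factor_mean", "must be >= 1")
  if (cfg$detour_factor_sd < 0) fail("detour_factor_sd", "must be >= 0")
  if (cfg$window_end < cfg$window_start) {
    fail("window_end", "must not precede window_start")
  }
  invisible(cfg)
}

## Truncated-normal quantile sampler: exact inverse-CDF draws on [lo, hi],
## one uniform per value, so streams stay reproducible and vector-stable.
rtruncnorm_q <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic telemedicine session population
#'
#' Draws `n_sessions` records with the statistical structure described by
#' the configuration: region, bimodal duration, provider/patient coordinate
#' pairs whose geodesic separation follows the per-region log-normal law
#' (patients are placed at a random bearing and the sampled distance from
#' the provider, so the configured distance is exact by construction),
#' timestamps respecting weekday and peak-hour shares, and a small planted
#' fraction of records violating the inclusion rules.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `session_id`, `start_utc` (POSIXct, UTC),
#'   `duration_min`, `n_participants`, `provider_lat`, `provider_lon`,
#'   `patient_lat`, `patient_lon`, `region`.
#' @examples
#' sessions <- generate_sessions(generator_config(n_sessions = 100, seed = 7))
#' @export
generate_sessions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- as.integer(config$n_sessions)
  if (n == 0L) return(empty_sessions())

  draw <- function(component, expr) {
    set.seed(seed_stream(config$seed, component))
    expr()
  }

  region <- draw("region", function() {
    sample(REGIONS, n, replace = TRUE, prob = config$region_shares[REGIONS])
  })

  mix <- config$duration_mix
  duration_min <- draw("duration", function() {
    short <- runif(n) < config$short_duration_share
    d <- numeric(n)
    d[short] <- rtruncnorm_q(sum(short), mix[["short_mean"]],
                             mix[["short_sd"]], 5, 30)
    d[!short] <- rtruncnorm_q(sum(!short), mix[["long_mean"]],
                              mix[["long_sd"]], 30 + 1e-9, 120)
    round(d, 2)
  })

  provider <- draw("provider_loc", function() {
    lat <- numeric(n)
    lon <- numeric(n)
    for (r in REGIONS) {
      idx <- which(region == r)
      box <- REGION_BOXES[[r]]
      lat[idx] <- runif(length(idx), box[1], box[2])
      lon[idx] <- runif(length(idx), box[3], box[4])
    }
    list(lat = lat, lon = lon)
  })

  geodesic <- draw("distance", function() {
    d <- numeric(n)
    for (r in REGIONS) {
      idx <- which(region == r)
      pars <- config$distance_params[[r]]
      d[idx] <- rlnorm(length(idx), pars[["meanlog"]], pars[["sdlog"]])
    }
    d
  })

  patient <- draw("bearing", function() {
    destination_point(provider$lat, provider$lon,
                      runif(n, 0, 2 * pi), geodesic)
  })

  start_utc <- draw("timestamp", function() {
    days <- seq(config$window_start, config$window_end, by = "day")
    wd <- as.integer(format(days, "%u")) # ISO weekday, 1 = Monday
    shares <- unname(config$weekday_shares[c("Mon", "Tue", "Wed", "Thu",
                                             "Fri", "Sat", "Sun")])
    w <- shares[wd] / tabulate(wd, nbins = 7)[wd]
    day <- sample(days, n, replace = TRUE, prob = w)
    peak <- runif(n) < config$peak_hour_share
    hour <- ifelse(peak, 13 + floor(runif(n) * 11), floor(runif(n) * 13))
    secs <- floor(runif(n) * 3600)
    as.POSIXct(day, tz = "UTC") + hour * 3600 + secs
  })

  sessions <- tibble::tibble(
    session_id = sprintf("S%08d", seq_len(n)),
    start_utc = start_utc,
    duration_min = duration_min,
    n_participants = 2L,
    provider_lat = provider$lat,
    provider_lon = provider$lon,
    patient_lat = patient$lat,
    patient_lon = patient$lon,
    region = region
  )

  n_bad <- floor(config$violation_rate * n)
  if (n_bad > 0) {
    sessions <- draw("violations", function() {
      bad <- sample.int(n, n_bad)
      kind <- rep_len(c("duration_low", "duration_high",
                        "participants", "missing_region"), n_bad)
      i <- bad[kind == "duration_low"]
      sessions$duration_min[i] <- round(runif(length(i), 0.5, 4.9), 2)
      i <- bad[kind == "duration_high"]
      sessions$duration_min[i] <- round(runif(length(i), 120.5, 180), 2)
      i <- bad[kind == "participants"]
      sessions$n_participants[i] <- sample(3:5, length(i), replace = TRUE)
      i <- bad[kind == "missing_region"]
      sessions$region[i] <- NA_character_
      sessions
    })
  }
  sessions
}

empty_sessions <- function() {
  tibble::tibble(
    session_id = character(), start_utc = as.POSIXct(character(), tz = "UTC"),
    duration_min = numeric(), n_participants = integer(),
    provider_lat = numeric(), provider_lon = numeric(),
    patient_lat = numeric(), patient_lon = numeric(), region = character()
  )
}

#' Synthetic road-routing oracle
#'
#' A deterministic stand-in for a car-routing distance-matrix service. Each
#' point pair receives a road distance equal to its geodesic distance times
#' a detour (circuity) factor drawn from a normal distribution truncated at
#' 1, so road distance never falls below geodesic distance; the factor is a
#' pure function of the seed and the coordinate pair, so identical queries
#' always return identical answers regardless of call order. Travel time is
#' road distance divided by a fixed average speed.
#'
#' @param detour_factor_mean Mean circuity factor (road/geodesic); >= 1.
#'   The default 1.3 is typical of the US road network.
#' @param detour_factor_sd SD of the circuity factor; >= 0.
#' @param speed_mph Average door-to-door car speed used to synthesise
#'   travel time, in miles per hour.
#' @param seed Integer seed entering the per-pair hash.
#' @return An object of class `synthetic_router` usable with [route()].
#' @export
synthetic_router <- function(detour_factor_mean = 1.3,
                             detour_factor_sd = 0.1,
                             speed_mph = 45,
                             seed = 1L) {
  if (detour_factor_mean < 1) {
    stop("`detour_factor_mean` must be >= 1", call. = FALSE)
  }
  if (detour_factor_sd < 0) stop("`detour_factor_sd` must be >= 0", call. = FALSE)
  if (speed_mph <= 0) stop("`speed_mph` must be > 0", call. = FALSE)
  structure(
    list(detour_factor_mean = detour_factor_mean,
         detour_factor_sd = detour_factor_sd,
         speed_mph = speed_mph, seed = as.integer(seed)),
    class = "synthetic_router"
  )
}

#' Query a router for one-way road distance and travel time
#'
#' The routing contract behind travel estimation: given origin and
#' destination coordinates it returns one-way road miles and one-way travel
#' hours, with road miles never below the geodesic distance between the
#' same points. Implementations are selected by the class of `router`.
#'
#' @param router A router object, e.g. from [synthetic_router()].
#' @param origin_lat,origin_lon,dest_lat,dest_lon Coordinate vectors in
#'   decimal degrees, recycled to a common length.
#' @return A tibble with columns `road_miles` and `travel_hours`.
#' @examples
#' r <- synthetic_router(seed = 1)
#' route(r, 40.7, -74.0, 40.8, -73.9)
#' @export
route <- function(router, origin_lat, origin_lon, dest_lat, dest_lon) {
  UseMethod("route")
}

#' @export
route.synthetic_router <- function(router, origin_lat, origin_lon,
                                   dest_lat, dest_lon) {
  geodesic <- haversine_miles(origin_lat, origin_lon, dest_lat, dest_lon)
  if (router$detour_factor_sd == 0) {
    factor <- rep(router$detour_factor_mean, length(geodesic))
  } else {
    u <- hash_unit(origin_lat, origin_lon, dest_lat, dest_lon,
                   seed = router$seed)
    p_lo <- pnorm(1, router$detour_factor_mean, router$detour_factor_sd)
    factor <- qnorm(p_lo + u * (1 - p_lo),
                    router$detour_factor_mean, router$detour_factor_sd)
  }
  road <- geodesic * factor
  tibble::tibble(road_miles = road, travel_hours = road / router$speed_mph)
}

#' Write or read a session table as CSV
#'
#' The on-disk schema is the documented nine-column header
#' `session_id, start_utc, duration_min, n_participants, provider_lat,
#' provider_lon, patient_lat, patient_lon, region`, with `start_utc` in
#' ISO-8601 UTC. [read_sessions()] validates the header, parses each row,
#' and flags (never silently drops) malformed rows — out-of-range
#' coordinates, non-positive durations, participant counts below 1, or
#' unparseable timestamps — in a `malformed_reason` column; the count is
#' also attached as attribute `n_malformed`.
#'
#' @param sessions A session tibble as produced by [generate_sessions()].
#' @param path File path.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns the session tibble with a `malformed_reason` column.
#' @export
write_sessions <- function(sessions, path) {
  out <- sessions
  out$start_utc <- format(out$start_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out[, SESSION_COLUMNS], path, na = "")
  invisible(path)
}

SESSION_COLUMNS <- c(
  "session_id", "start_utc", "duration_min", "n_participants",
  "provider_lat", "provider_lon", "patient_lat", "patient_lon", "region"
)

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("session file not found: %s", path), call. = FALSE)
  }
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(SESSION_COLUMNS, header)
  if (length(missing_cols) > 0) {
    stop(sprintf("session file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      start_utc = readr::col_character(),
      duration_min = readr::col_double(),
      n_participants = readr::col_integer(),
      provider_lat = readr::col_double(),
      provider_lon = readr::col_double(),
      patient_lat = readr::col_double(),
      patient_lon = readr::col_double(),
      region = readr::col_character()
    ),
    na = c("", "NA")
  )
  raw <- raw[, SESSION_COLUMNS]
  start <- as.POSIXct(raw$start_utc, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, label) {
    ifelse(is.na(reason) & cond, label, reason)
  }
  bad_coord <- function(lat, lon) {
    is.na(lat) | is.na(lon) | lat < -90 | lat > 90 | lon < -180 | lon > 180
  }
  reason <- flag(is.na(start) & !is.na(raw$start_utc) |
                   is.na(raw$start_utc), "bad_timestamp")
  reason <- flag(is.na(raw$duration_min) | raw$duration_min <= 0,
                 "bad_duration")
  reason <- flag(is.na(raw$n_participants) | raw$n_participants < 1,
                 "bad_participants")
  reason <- flag(bad_coord(raw$provider_lat, raw$provider_lon),
                 "bad_provider_coordinates")
  reason <- flag(bad_coord(raw$patient_lat, raw$patient_lon),
                 "bad_patient_coordinates")

  out <- raw
  out$start_utc <- start
  out$malformed_reason <- reason
  attr(out, "n_malformed") <- sum(!is.na(reason))
  out
}
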