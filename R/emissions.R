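#' Emission and conversion factors
#'
#' Every constant of the emissions model in one configurable record, so a
#' sensitivity analysis is a configuration sweep rather than a code change.
#'
#' Defaults: 404 g CO2 per vehicle-mile (US EPA 2022 average passenger
#' vehicle at 22.0 miles per gallon); 0.036 GB of data per minute of 720p
#' two-participant videoconferencing; 0.015 kWh per GB transmitted
#' (fixed-line network energy intensity); 4.33e-4 metric tons CO2 per kWh
#' (US grid conversion rate); car mode share 0.848 (adult commuting
#' patterns); 1e6 grams per metric ton.
#'
#' @param g_co2_per_mile Tailpipe grams CO2 per vehicle-mile.
#' @param gb_per_min Data volume per minute of two-party HD video, GB/min.
#' @param kwh_per_gb Transmission energy per GB, kWh/GB.
#' @param t_co2_per_kwh Grid emission factor, metric tons CO2 per kWh.
#' @param car_share Fraction of avoided travel by car, in (0, 1].
#' @return A validated list of class `emission_factors`.
#' @export
emission_factors <- function(g_co2_per_mile = 404,
                             gb_per_min = 0.036,
                             kwh_per_gb = 0.015,
                             t_co2_per_kwh = 4.33e-4,
                             car_share = 0.848) {
  f <- list(
    g_co2_per_mile = g_co2_per_mile, gb_per_min = gb_per_min,
    kwh_per_gb = kwh_per_gb, t_co2_per_kwh = t_co2_per_kwh,
    car_share = car_share, grams_per_metric_ton = 1e6
  )
  for (nm in c("g_co2_per_mile", "gb_per_min", "kwh_per_gb", "t_co2_per_kwh")) {
    if (!is.numeric(f[[nm]]) || f[[nm]] <= 0) {
      stop(sprintf("`%s` must be strictly positive", nm), call. = FALSE)
    }
  }
  if (car_share <= 0 || car_share > 1) {
    stop("`car_share` must lie in (0, 1]", call. = FALSE)
  }
  structure(f, class = "emission_factors")
}

#' Avoided-travel CO2 savings in grams
#'
#' Tailpipe emissions avoided by not driving: miles times the per-mile
#' emission factor. Linear and homogeneous in distance.
#'
#' @param round_trip_miles Round-trip car miles avoided; non-negative.
#' @param factors An [emission_factors()] record.
#' @return Grams of CO2, same length as `round_trip_miles`.
#' @examples
#' travel_savings_g(49.05) # ~19,816 g for the median round trip
#' @export
travel_savings_g <- function(round_trip_miles, factors = emission_factors()) {
  stopifnot(inherits(factors, "emission_factors"))
  if (any(round_trip_miles < 0, na.rm = TRUE)) {
    stop("`round_trip_miles` must be non-negative", call. = FALSE)
  }
  round_trip_miles * factors$g_co2_per_mile
}

#' Videoconferencing CO2 expenditure in grams
#'
#' The energy cost of holding the session rather than travelling: session
#' minutes are converted to data volume (GB/min), data volume to
#' transmission energy (kWh/GB), energy to CO2 mass (metric tons/kWh), and
#' tons to grams. Strictly increasing and linear in duration; with the
#' default factors, one minute of video costs
#' 0.036 x 0.015 x 4.33e-4 x 1e6 = 0.23382 g CO2.
#'
#' @param duration_min Session duration in minutes; non-negative.
#' @param factors An [emission_factors()] record.
#' @return Grams of CO2, same length as `duration_min`.
#' @examples
#' session_expenditure_g(36.73) # ~8.59 g at the median session duration
#' @export
session_expenditure_g <- function(duration_min, factors = emission_factors()) {
  stopifnot(inherits(factors, "emission_factors"))
  if (any(duration_min < 0, na.rm = TRUE)) {
    stop("`duration_min` must be non-negative", call. = FALSE)
  }
  duration_min * factors$gb_per_min * factors$kwh_per_gb *
    factors$t_co2_per_kwh * factors$grams_per_metric_ton
}

#' Net per-session emissions accounting
#'
#' Composes the savings and expenditure chains: `savings_g` from the
#' chosen travel-distance basis, `expenditure_g` from duration,
#' `net_g = savings_g - expenditure_g` exactly (possibly negative for
#' zero-travel sessions, which still consume energy), and
#' `net_per_min_g = net_g / duration_min` (defined as 0 for zero
#' duration, which the filters rule out anyway).
#'
#' The `miles_basis` switch selects whether savings use the raw round-trip
#' road miles (the default, matching the per-session accounting the
#' summary tables are built on) or the car-mode-share-adjusted miles; the
#' adjustment can alternatively be applied once at the aggregate level.
#'
#' @param travel A tibble from [estimate_travel()] (needs
#'   `round_trip_miles` and `adjusted_round_trip_miles`).
#' @param duration_min Session durations in minutes, recycled against
#'   `travel` rows.
#' @param factors An [emission_factors()] record.
#' @param miles_basis `"round_trip"` or `"adjusted"`.
#' @return A tibble with columns `savings_g`, `expenditure_g`, `net_g`,
#'   `net_per_min_g`.
#' @export
net_session_emissions <- function(travel, duration_min,
                                  factors = emission_factors(),
                                  miles_basis = c("round_trip", "adjusted")) {
  miles_basis <- match.arg(miles_basis)
  miles <- switch(miles_basis,
    round_trip = travel$round_trip_miles,
    adjusted = travel$adjusted_round_trip_miles
  )
  savings <- travel_savings_g(miles, factors)
  expenditure <- session_expenditure_g(duration_min, factors)
  net <- savings - expenditure
  tibble::tibble(
    savings_g = savings,
    expenditure_g = expenditure,
    net_g = net,
    net_per_min_g = ifelse(duration_min > 0, net / duration_min, 0)
  )
}
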