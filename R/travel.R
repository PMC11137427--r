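#' Per-session travel estimates through the routing contract
#'
#' For each session, computes the one-way great-circle distance between the
#' provider and patient coordinates, queries the router for the one-way
#' road distance and travel time, doubles both to a round trip (a
#' distance-matrix query is one-way; the avoided journey is out and back),
#' and records the car-mode-share-adjusted round trip
#' (`round_trip_miles * car_share`). The adjustment is carried as its own
#' column rather than overwriting the round trip, so downstream emission
#' calculations can choose either basis explicitly.
#'
#' @param sessions A session tibble with provider/patient coordinates.
#' @param router A router satisfying the [route()] contract (road >=
#'   geodesic, deterministic per input), e.g. [synthetic_router()].
#' @param car_share Fraction of avoided travel assumed to occur by car; the
#'   default 0.848 is the adult car-commuting share in US survey data.
#' @return The input tibble with columns `geodesic_miles`,
#'   `oneway_road_miles`, `round_trip_miles`, `round_trip_hours`, and
#'   `adjusted_round_trip_miles` appended (replacing any existing columns
#'   of those names).
#' @examples
#' s <- generate_sessions(generator_config(n_sessions = 5, seed = 2))
#' estimate_travel(s, synthetic_router(seed = 2))
#' @export
estimate_travel <- function(sessions, router, car_share = 0.848) {
  stopifnot(is.data.frame(sessions))
  if (car_share <= 0 || car_share > 1) {
    stop("`car_share` must lie in (0, 1]", call. = FALSE)
  }
  geodesic <- haversine_miles(sessions$provider_lat, sessions$provider_lon,
                              sessions$patient_lat, sessions$patient_lon)
  routed <- route(router, sessions$provider_lat, sessions$provider_lon,
                  sessions$patient_lat, sessions$patient_lon)
  out <- sessions
  out$geodesic_miles <- geodesic
  out$oneway_road_miles <- routed$road_miles
  out$round_trip_miles <- 2 * routed$road_miles
  out$round_trip_hours <- 2 * routed$travel_hours
  out$adjusted_round_trip_miles <- out$round_trip_miles * car_share
  out
}
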