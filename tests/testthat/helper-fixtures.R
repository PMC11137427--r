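# Shared fixture builders and independent oracles.

# Minimal valid session row(s); override any field via ...
make_sessions <- function(n = 1, ...) {
  base <- tibble::tibble(
    session_id = sprintf("F%04d", seq_len(n)),
    start_utc = rep(as.POSIXct("2022-06-15 15:00:00", tz = "UTC"), n),
    duration_min = rep(30, n),
    n_participants = rep(2L, n),
    provider_lat = rep(40.0, n),
    provider_lon = rep(-75.0, n),
    patient_lat = rep(40.1, n),
    patient_lon = rep(-75.1, n),
    region = rep("Northeast", n)
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# Brute-force great-circle oracle: numerically integrate along the circle by
# summing chord lengths of a fine slerp polyline between the two unit
# vectors. Independent of the haversine closed form.
brute_force_gc_miles <- function(lat1, lon1, lat2, lon2, steps = 5000,
                                 radius = 3958.8) {
  to_rad <- pi / 180
  unit <- function(lat, lon) {
    c(cos(lat * to_rad) * cos(lon * to_rad),
      cos(lat * to_rad) * sin(lon * to_rad),
      sin(lat * to_rad))
  }
  u <- unit(lat1, lon1)
  v <- unit(lat2, lon2)
  t <- seq(0, 1, length.out = steps + 1)
  # slerp path, renormalised at every step
  pts <- sapply(t, function(ti) {
    p <- (1 - ti) * u + ti * v
    nrm <- sqrt(sum(p^2))
    if (nrm < 1e-12) return(u) # antipodal guard; callers avoid this case
    p / nrm
  })
  chords <- sqrt(colSums((pts[, -1, drop = FALSE] -
                            pts[, -ncol(pts), drop = FALSE])^2))
  radius * sum(2 * asin(pmin(chords / 2, 1)))
}

# Random valid coordinate pairs (away from the poles and the antimeridian so
# the brute-force oracle stays well-conditioned).
random_point_pairs <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    lat1 = runif(n, -80, 80), lon1 = runif(n, -170, 170),
    lat2 = runif(n, -80, 80), lon2 = runif(n, -170, 170)
  )
}
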