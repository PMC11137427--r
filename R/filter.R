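#' Apply the clinical-encounter inclusion and exclusion rules
#'
#' Retains sessions that satisfy all of: exactly two participants (a
#' patient-provider dyad); duration between 5 and 120 minutes, both
#' endpoints inclusive; start timestamp inside the study window; one-way
#' geodesic distance at most `max_geodesic_miles` (<= semantics, so exactly
#' 400 miles is retained); and a known region. Sub-5-minute calls are
#' treated as connection tests rather than clinical encounters, and
#' sessions over two hours as remote monitoring; the geodesic cutoff
#' removes extreme distances that would not plausibly have been travelled.
#'
#' Rules are evaluated in the fixed order dyad, duration-low,
#' duration-high, window, geodesic, missing-region, and every excluded
#' record is attributed to the first rule it fails, so exclusion counts are
#' deterministic and sum exactly to `n_input - n_retained`. Rows flagged as
#' malformed by [read_sessions()] are excluded first under a `malformed`
#' rule. Filtering never raises on a rule violation; it counts it.
#'
#' @param sessions A session tibble ([generate_sessions()] /
#'   [read_sessions()] schema).
#' @param date_window Length-2 vector of inclusive date bounds for session
#'   start.
#' @param max_geodesic_miles One-way great-circle cutoff in miles.
#' @return A list with `sessions` (retained rows, plus a `geodesic_miles`
#'   column) and `report`, a `filter_report` with fields `n_input`,
#'   `n_retained` and per-rule `exclusions`.
#' @examples
#' s <- generate_sessions(generator_config(n_sessions = 500, seed = 3))
#' f <- apply_filters(s)
#' f$report
#' @export
apply_filters <- function(sessions,
                          date_window = c("2022-01-01", "2023-02-21"),
                          max_geodesic_miles = 400) {
  stopifnot(is.data.frame(sessions))
  window_lo <- as.POSIXct(paste(date_window[1], "00:00:00"), tz = "UTC")
  window_hi <- as.POSIXct(as.Date(date_window[2]) + 1, tz = "UTC")

  n_input <- nrow(sessions)
  rules <- c("malformed", "not_dyad", "duration_below_5min",
             "duration_above_120min", "outside_date_window",
             "geodesic_above_cutoff", "missing_region")
  if (n_input == 0) {
    report <- new_filter_report(0L, 0L, setNames(rep(0L, length(rules)), rules))
    out <- sessions
    out$geodesic_miles <- numeric(0)
    return(list(sessions = out, report = report))
  }

  malformed <- if ("malformed_reason" %in% names(sessions)) {
    !is.na(sessions$malformed_reason)
  } else {
    rep(FALSE, n_input)
  }
  geodesic <- rep(NA_real_, n_input)
  ok_coords <- !malformed
  geodesic[ok_coords] <- haversine_miles(
    sessions$provider_lat[ok_coords], sessions$provider_lon[ok_coords],
    sessions$patient_lat[ok_coords], sessions$patient_lon[ok_coords]
  )

  ## First-failing-rule attribution, in the documented fixed order.
  reason <- rep(NA_character_, n_input)
  hit <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- hit(malformed, "malformed")
  reason <- hit(sessions$n_participants != 2L, "not_dyad")
  reason <- hit(sessions$duration_min < 5, "duration_below_5min")
  reason <- hit(sessions$duration_min > 120, "duration_above_120min")
  reason <- hit(sessions$start_utc < window_lo | sessions$start_utc >= window_hi,
                "outside_date_window")
  ## <= semantics at the cutoff; the 1e-9-mile slack keeps sessions at
  ## exactly the boundary from being excluded by floating-point noise.
  reason <- hit(geodesic > max_geodesic_miles + 1e-9, "geodesic_above_cutoff")
  reason <- hit(is.na(sessions$region) | !(sessions$region %in% REGIONS),
                "missing_region")

  keep <- is.na(reason)
  retained <- sessions[keep, , drop = FALSE]
  retained$geodesic_miles <- geodesic[keep]
  retained$malformed_reason <- NULL

  exclusions <- vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                       integer(1))
  report <- new_filter_report(n_input, sum(keep), exclusions)
  list(sessions = retained, report = report)
}

new_filter_report <- function(n_input, n_retained, exclusions) {
  stopifnot(n_input == n_retained + sum(exclusions))
  structure(
    list(n_input = as.integer(n_input), n_retained = as.integer(n_retained),
         exclusions = as.list(exclusions)),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Session filter: %d of %d retained (%.2f%%)\n",
              x$n_retained, x$n_input,
              if (x$n_input > 0) 100 * x$n_retained / x$n_input else 100))
  for (r in names(x$exclusions)) {
    if (x$exclusions[[r]] > 0) {
      cat(sprintf("  excluded %-22s %d\n", paste0(r, ":"), x$exclusions[[r]]))
    }
  }
  invisible(x)
}
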