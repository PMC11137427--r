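#' Stratum assignment for proportional sampling
#'
#' Each filtered session belongs to exactly one of 40 strata: region (5
#' levels) by duration class (short = 5-30 minutes inclusive, long = over
#' 30 up to 120) by day class (weekday = Monday-Friday, weekend = Saturday
#' and Sunday, in UTC calendar terms) by hour class (peak = 13:00-23:59
#' UTC, off-peak otherwise). A duration of exactly 30 minutes is short; a
#' start at exactly 13:00 UTC is peak.
#'
#' @param sessions A session tibble (rows that passed [apply_filters()]).
#' @return The input with added factor columns `duration_class`
#'   (`short`/`long`), `day_class` (`weekday`/`weekend`), `hour_class`
#'   (`peak`/`offpeak`), and a `stratum` key string
#'   `region/duration/day/hour`.
#' @export
assign_stratum <- function(sessions) {
  stopifnot(is.data.frame(sessions))
  wd <- as.integer(format(sessions$start_utc, "%u", tz = "UTC"))
  hr <- as.integer(format(sessions$start_utc, "%H", tz = "UTC"))
  out <- sessions
  out$duration_class <- factor(ifelse(sessions$duration_min <= 30, "short", "long"),
                               levels = c("short", "long"))
  out$day_class <- factor(ifelse(wd >= 6, "weekend", "weekday"),
                          levels = c("weekday", "weekend"))
  out$hour_class <- factor(ifelse(hr >= 13, "peak", "offpeak"),
                           levels = c("peak", "offpeak"))
  out$stratum <- paste(out$region, out$duration_class, out$day_class,
                       out$hour_class, sep = "/")
  out
}

## All 40 stratum keys in the canonical total ordering used for
## deterministic tie-breaking: region alphabetical, then short < long,
## weekday < weekend, peak < offpeak.
stratum_keys <- function() {
  g <- expand.grid(
    hour_class = c("peak", "offpeak"),
    day_class = c("weekday", "weekend"),
    duration_class = c("short", "long"),
    region = REGIONS,
    stringsAsFactors = FALSE
  )[, 4:1]
  paste(g$region, g$duration_class, g$day_class, g$hour_class, sep = "/")
}

#' Census of stratum population sizes
#'
#' @param sessions Output of [assign_stratum()].
#' @return A tibble with `stratum` (all 40 keys, canonical order) and
#'   `n_pop` counts summing to `nrow(sessions)`.
#' @export
stratum_census <- function(sessions) {
  keys <- stratum_keys()
  counts <- table(factor(sessions$stratum, levels = keys))
  tibble::tibble(stratum = keys, n_pop = as.integer(counts))
}

#' Proportional (largest-remainder) sample allocation
#'
#' Apportions `sample_size` draws across strata proportionally to their
#' population counts using the largest-remainder (Hamilton) method: each
#' stratum receives the floor of its exact quota, then the remaining units
#' go to the strata with the largest fractional remainders, ties broken by
#' the canonical stratum ordering. The result always sums exactly to
#' `sample_size` and distorts no stratum share by a full unit of
#' `1/sample_size`.
#'
#' @param census A tibble with columns `stratum` and `n_pop` (e.g. from
#'   [stratum_census()]).
#' @param sample_size Total number of sessions to sample; at most
#'   `sum(n_pop)`.
#' @return The census with an added `n_sample` column.
#' @examples
#' census <- tibble::tibble(stratum = c("a", "b", "c"), n_pop = c(10, 10, 10))
#' allocate_proportional(census, 10)$n_sample # 4 3 3
#' @export
allocate_proportional <- function(census, sample_size) {
  stopifnot(is.data.frame(census), all(c("stratum", "n_pop") %in% names(census)))
  total <- sum(census$n_pop)
  if (sample_size > total) {
    stop(sprintf("sample_size (%d) exceeds population size (%d)",
                 sample_size, total), call. = FALSE)
  }
  if (sample_size < 0) stop("sample_size must be non-negative", call. = FALSE)
  quota <- census$n_pop * sample_size / total
  base <- floor(quota)
  remainder <- quota - base
  leftover <- as.integer(round(sample_size - sum(base)))
  n_sample <- as.integer(base)
  if (leftover > 0) {
    topup <- order(-remainder, seq_len(nrow(census)))[seq_len(leftover)]
    n_sample[topup] <- n_sample[topup] + 1L
  }
  stopifnot(sum(n_sample) == sample_size, all(n_sample <= census$n_pop))
  out <- census
  out$n_sample <- n_sample
  out
}

#' Draw a stratified random sample
#'
#' Simple random sampling without replacement within each stratum, at the
#' allocated counts. Rows are ordered by `session_id` within a stratum
#' before drawing, so the result depends only on the record set and the
#' seed, not on input row order.
#'
#' @param sessions Output of [assign_stratum()].
#' @param allocation Output of [allocate_proportional()].
#' @param seed Integer seed for the draw.
#' @return A tibble of sampled sessions with `sum(allocation$n_sample)`
#'   rows.
#' @export
draw_sample <- function(sessions, allocation, seed = 1L) {
  stopifnot(is.data.frame(sessions), "stratum" %in% names(sessions),
            all(c("stratum", "n_sample") %in% names(allocation)))
  pop <- table(factor(sessions$stratum, levels = allocation$stratum))
  short <- allocation$n_sample > as.integer(pop)
  if (any(short)) {
    stop(sprintf("allocation infeasible for stratum %s: %d requested, %d available",
                 allocation$stratum[which(short)[1]],
                 allocation$n_sample[which(short)[1]],
                 as.integer(pop)[which(short)[1]]), call. = FALSE)
  }
  ord <- order(sessions$stratum, sessions$session_id)
  sessions <- sessions[ord, , drop = FALSE]
  set.seed(as.integer(seed))
  picked <- integer(0)
  row_idx <- split(seq_len(nrow(sessions)), sessions$stratum)
  for (i in seq_len(nrow(allocation))) {
    key <- allocation$stratum[i]
    k <- allocation$n_sample[i]
    if (k == 0L) next
    idx <- row_idx[[key]]
    picked <- c(picked, if (length(idx) == k) idx else sort(sample(idx, k)))
  }
  sessions[picked, , drop = FALSE]
}
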