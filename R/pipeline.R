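#' Pipeline configuration
#'
#' One validated record driving the whole analysis: input source (a
#' [generator_config()] or a CSV path), filter thresholds, sampling
#' parameters, router, emission factors, extrapolation inputs, and an
#' optional output directory. Unknown arguments are rejected.
#'
#' @param input A `generator_config` (synthetic population) or a path to a
#'   session CSV in the [write_sessions()] schema.
#' @param date_window,max_geodesic_miles Filter thresholds; see
#'   [apply_filters()].
#' @param sample_size Proportional sample size; `NULL` analyses the full
#'   retained population.
#' @param seed Seed for the sample draw.
#' @param router A router for [estimate_travel()]; defaults to a
#'   [synthetic_router()] sharing `seed`.
#' @param factors An [emission_factors()] record.
#' @param miles_basis Savings basis for [net_session_emissions()].
#' @param central Central estimate for extrapolation, `"median"` or
#'   `"mean"`.
#' @param cms_sessions,cms_share,platform_sessions Extrapolation inputs;
#'   `platform_sessions = NULL` uses the pipeline's own retained count.
#' @param out_dir Directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = generator_config(),
                            date_window = c("2022-01-01", "2023-02-21"),
                            max_geodesic_miles = 400,
                            sample_size = NULL,
                            seed = 1L,
                            router = NULL,
                            factors = emission_factors(),
                            miles_basis = c("round_trip", "adjusted"),
                            central = c("median", "mean"),
                            cms_sessions = 27691878,
                            cms_share = 0.38,
                            platform_sessions = NULL,
                            out_dir = NULL) {
  miles_basis <- match.arg(miles_basis)
  central <- match.arg(central)
  if (!inherits(input, "generator_config") &&
      !(is.character(input) && length(input) == 1)) {
    stop("`input` must be a generator_config or a CSV path", call. = FALSE)
  }
  if (is.null(router)) {
    router <- if (inherits(input, "generator_config")) {
      synthetic_router(input$detour_factor_mean, input$detour_factor_sd,
                       seed = input$seed)
    } else {
      synthetic_router(seed = seed)
    }
  }
  stopifnot(inherits(factors, "emission_factors"))
  if (!is.null(sample_size) &&
      (sample_size < 1 || sample_size != floor(sample_size))) {
    stop("`sample_size` must be a positive integer or NULL", call. = FALSE)
  }
  structure(
    list(input = input, date_window = date_window,
         max_geodesic_miles = max_geodesic_miles,
         sample_size = sample_size, seed = as.integer(seed),
         router = router, factors = factors, miles_basis = miles_basis,
         central = central, cms_sessions = cms_sessions,
         cms_share = cms_share, platform_sessions = platform_sessions,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full emissions-accounting pipeline
#'
#' Executes the stages in order — generate or ingest, filter, stratify,
#' allocate and draw the proportional sample, estimate travel, compute
#' per-session emissions, summarise, extrapolate nationally — and returns
#' a manifest of record counts, summary tables and the headline national
#' estimate. With `out_dir` set, stage artifacts (session tables, summary
#' CSVs, the manifest JSON) are written there; no stage ever mutates an
#' upstream artifact. Two runs with identical configuration and seed are
#' identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_manifest`: `counts` (per-stage record
#'   counts), `filter_report`, `allocation`, `summaries` (distance,
#'   duration and emissions tables), `national`, and `config_fingerprint`.
#' @examples
#' \donttest{
#' m <- run_pipeline(pipeline_config(
#'   input = generator_config(n_sessions = 2000, seed = 9),
#'   sample_size = 500, seed = 9
#' ))
#' m$national
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  sessions <- if (inherits(config$input, "generator_config")) {
    generate_sessions(config$input)
  } else {
    read_sessions(config$input)
  }
  n_input <- nrow(sessions)

  filtered <- apply_filters(sessions, config$date_window,
                            config$max_geodesic_miles)
  retained <- assign_stratum(filtered$sessions)

  census <- stratum_census(retained)
  if (!is.null(config$sample_size)) {
    allocation <- allocate_proportional(census, config$sample_size)
    analytic <- draw_sample(retained, allocation, config$seed)
  } else {
    allocation <- census
    allocation$n_sample <- allocation$n_pop
    analytic <- retained
  }

  analytic <- estimate_travel(analytic, config$router,
                              config$factors$car_share)
  emissions <- net_session_emissions(analytic, analytic$duration_min,
                                     config$factors, config$miles_basis)
  analytic <- dplyr::bind_cols(analytic, emissions)

  summaries <- list(
    distance_by_region = grouped_summary(analytic, "round_trip_miles", "region"),
    distance_by_day = grouped_summary(analytic, "round_trip_miles", "day_class"),
    distance_by_length = grouped_summary(analytic, "round_trip_miles",
                                         "duration_class"),
    travel_emissions = dplyr::bind_rows(lapply(
      c("round_trip_hours", "round_trip_miles", "savings_g", "duration_min",
        "expenditure_g", "net_g", "net_per_min_g"),
      function(v) dplyr::bind_cols(tibble::tibble(quantity = v),
                                   summarize_values(analytic[[v]]))
    ))
  )

  central_value <- if (config$central == "median") {
    median(analytic$net_g)
  } else {
    mean(analytic$net_g)
  }
  national <- national_estimate(
    central_value, config$central, config$cms_sessions, config$cms_share,
    platform_sessions = config$platform_sessions %||% filtered$report$n_retained
  )

  manifest <- structure(
    list(
      counts = list(
        n_input = n_input,
        n_malformed = attr(sessions, "n_malformed") %||% 0L,
        n_retained = filtered$report$n_retained,
        n_sampled = nrow(analytic)
      ),
      filter_report = filtered$report,
      allocation = allocation,
      summaries = summaries,
      national = national,
      config_fingerprint = config_fingerprint(config)
    ),
    class = "pipeline_manifest"
  )

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(config$out_dir, analytic, manifest)
  }
  manifest
}

## Cheap deterministic fingerprint of the serialized configuration, for
## provenance in the manifest (not a cryptographic hash).
config_fingerprint <- function(config) {
  s <- deparse(config[setdiff(names(config), "out_dir")])
  h <- 0
  for (b in utf8ToInt(paste(s, collapse = "\n"))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_pipeline_outputs <- function(out_dir, analytic, manifest) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- analytic
  out$start_utc <- format(out$start_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, file.path(out_dir, "analytic_sessions.csv"), na = "")
  for (nm in names(manifest$summaries)) {
    readr::write_csv(manifest$summaries[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")))
  }
  readr::write_csv(manifest$allocation, file.path(out_dir, "allocation.csv"))
  jsonlite::write_json(
    list(
      counts = manifest$counts,
      exclusions = manifest$filter_report$exclusions,
      national = unclass(manifest$national),
      config_fingerprint = manifest$config_fingerprint
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Telemedicine emissions pipeline\n")
  cat(sprintf("  input records:    %d\n", x$counts$n_input))
  cat(sprintf("  retained:         %d\n", x$counts$n_retained))
  cat(sprintf("  analytic sample:  %d\n", x$counts$n_sampled))
  cat(sprintf("  config:           %s\n\n", x$config_fingerprint))
  print(x$national)
  invisible(x)
}
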