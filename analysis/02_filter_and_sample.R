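#!/usr/bin/env Rscript

# Stage 2: inclusion/exclusion filtering and stratified proportional
# sampling.
#
# Applies the encounter rules (dyad, 5-120 min, study window, <=400
# geodesic miles, known region), assigns each retained session to one of
# the 40 region x duration x day x hour strata, and draws a 79,904-session
# proportional sample by largest-remainder allocation.

suppressPackageStartupMessages(library(teleco2))

sample_size <- 79904
sample_seed <- 20240515

sessions <- read_sessions("scratch/sessions_raw.csv")
filtered <- apply_filters(sessions)
print(filtered$report)

retained <- assign_stratum(filtered$sessions)
census <- stratum_census(retained)
allocation <- allocate_proportional(census, sample_size)
analytic <- draw_sample(retained, allocation, seed = sample_seed)

dir.create("results", showWarnings = FALSE)
readr::write_csv(allocation, "results/allocation.csv")
jsonlite::write_json(
  list(n_input = filtered$report$n_input,
       n_retained = filtered$report$n_retained,
       exclusions = filtered$report$exclusions,
       sample_size = nrow(analytic)),
  "results/filter_report.json", auto_unbox = TRUE, pretty = TRUE
)
out <- analytic
out$start_utc <- format(out$start_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
readr::write_csv(out, "scratch/analytic_sample.csv", na = "")

cat(sprintf("\nRetained %s of %s sessions; sampled %s across %d non-empty strata\n",
            format(filtered$report$n_retained, big.mark = ","),
            format(filtered$report$n_input, big.mark = ","),
            format(nrow(analytic), big.mark = ","),
            sum(allocation$n_sample > 0)))
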