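#!/usr/bin/env Rscript

# Stage 4: national extrapolation.
#
# Scales the median per-session net savings to (a) the retained platform
# population and (b) the national annual session count implied by CMS
# reimbursement volume (27,691,878 sessions) at a 38% expenditure share.

suppressPackageStartupMessages(library(teleco2))

analytic <- readr::read_csv("scratch/analytic_with_emissions.csv",
                            show_col_types = FALSE)
counts <- jsonlite::read_json("results/filter_report.json")

est <- national_estimate(
  per_session_net_g = median(analytic$net_g),
  central = "median",
  platform_sessions = counts$n_retained
)
print(est)

jsonlite::write_json(unclass(est), "results/national_estimate.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nWrote results/national_estimate.json\n")
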