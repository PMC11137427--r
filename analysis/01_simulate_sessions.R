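#!/usr/bin/env Rscript

# Stage 1: simulate the session population.
#
# Draws a synthetic population of 1,000,000 telemedicine sessions with the
# observed platform structure (regional shares, bimodal durations,
# right-skewed per-region travel distances, weekday/peak-hour timing) and a
# 2% planted fraction of rule-violating records, then writes it to scratch/
# for the downstream stages.

suppressPackageStartupMessages(library(teleco2))

n_sessions <- 1e6
master_seed <- 20240515

cfg <- generator_config(n_sessions = n_sessions, seed = master_seed)
cat(sprintf("Simulating %s sessions (seed %d)...\n",
            format(n_sessions, big.mark = ","), master_seed))
sessions <- generate_sessions(cfg)

dir.create("scratch", showWarnings = FALSE)
write_sessions(sessions, "scratch/sessions_raw.csv")

cat(sprintf("Wrote scratch/sessions_raw.csv (%s rows)\n",
            format(nrow(sessions), big.mark = ",")))
cat("Region shares (%):\n")
print(round(100 * prop.table(table(sessions$region)), 2))
valid <- sessions$duration_min >= 5 & sessions$duration_min <= 120
cat(sprintf("Short-duration share among eligible sessions: %.2f%%\n",
            100 * mean(sessions$duration_min[valid] <= 30)))
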