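#!/usr/bin/env Rscript

## Step 1 — generate the synthetic spontaneous-reporting database used by
## the whole workflow: 50,000 cases over 2020Q3-2024Q2, 210 preferred
## terms of which 10 carry a planted relative risk of 4 for the target
## drug, 10% injected duplicate case versions, and Weibull(86.8, 0.617)
## onset times for target-drug cases.

suppressPackageStartupMessages(library(faersignal))

seed <- 20260925L
raw_dir <- "results/raw_faers"
planted <- data.frame(pt_id = c(5L, 27L, 49L, 71L, 93L, 115L, 137L, 159L,
                                181L, 203L),
                      rr = 4)

cfg <- sim_config(n_cases = 50000L, n_pts = 210L, planted_signals = planted,
                  duplicate_frac = 0.1, seed = seed)
db <- generate_database(cfg)
paths <- write_faers_tables(db, raw_dir)

cat("Wrote FAERS-dialect tables to", raw_dir, "\n")
cat(sprintf("  cases: %d (plus %d duplicate versions)\n",
            cfg$n_cases, nrow(db$truth$duplicates)))
cat(sprintf("  target-drug cases: %d\n", length(db$truth$target_caseids)))
cat(sprintf("  planted signals: %d PTs at RR %.0f\n",
            nrow(planted), planted$rr[1]))
cat("Ground truth sidecar:", unname(paths["truth"]), "\n")
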