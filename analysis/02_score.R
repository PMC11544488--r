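#!/usr/bin/env Rscript
# Stage 2: compute MEWS, NEWS and NEWS2 streams for the simulated cohort.
#
# Each engine re-scores at every observation time with the latest
# carried-forward value of every component; NEWS2 applies its SpO2 scale-2
# rule from the first PaCO2 > 45 mm Hg charted with a concurrent
# FiO2 > 21%. One CSV per engine lands next to the cohort.

library(ewsbench)

cohort_dir <- "results/cohort"
if (!file.exists(file.path(cohort_dir, "observations.csv"))) {
  stop("run analysis/01_simulate.R first")
}
run_score(cohort_dir)
cat("Score streams written to", cohort_dir, "\n")
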