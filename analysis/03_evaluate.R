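#!/usr/bin/env Rscript
# Stage 3: head-to-head evaluation of the score streams.
#
# Aligns every stream to the dense reference grid (last observation
# carried forward), labels each aligned observation with the composite
# outcome within 24 h, and produces:
#   - auroc_by_campus.csv            bootstrapped AUROC (100 iterations,
#                                    one observation per encounter), pooled
#                                    and per campus
#   - delong_vs_reference.csv        paired DeLong comparison vs NEWS
#   - threshold_characteristics.csv  test characteristics at NEWS-matched
#                                    moderate (sens @ NEWS 5) and high
#                                    (spec @ NEWS 7) thresholds
#   - pr_curves.csv                  observation-level precision-recall
#   - efficiency_curves.csv          encounter-level alert burden vs catch
#   - encounter_comparison.csv       alerts, catches and lead times
#   - lead_times.csv                 trigger-to-event lead-time summaries

library(ewsbench)

seed <- as.integer(Sys.getenv("EWSBENCH_SEED", "1"))
cohort_dir <- "results/cohort"
out_dir <- "results/report"
if (!file.exists(file.path(cohort_dir, "scores_NEWS.csv"))) {
  stop("run analysis/02_score.R first")
}

cfg <- evaluation_config(horizon_hours = 24, outcome_type = "deterioration",
                         n_bootstrap = 100L, random_seed = seed)
res <- run_evaluate(cohort_dir, out_dir, cfg)

au <- res$auroc_by_campus
pooled <- au[au$campus == "All", ]
cat("Pooled bootstrapped AUROC (24 h composite deterioration):\n")
for (i in order(-pooled$auc)) {
  cat(sprintf("  %-6s %.3f (95%% CI %.3f-%.3f)\n", pooled$score_name[i],
              pooled$auc[i], pooled$ci_low[i], pooled$ci_high[i]))
}
cat("\nNEWS-matched thresholds:\n")
for (s in names(res$matched_thresholds)) {
  th <- res$matched_thresholds[[s]]
  cat(sprintf("  %-6s moderate >= %s, high >= %s\n", s,
              format(th[["moderate"]]), format(th[["high"]])))
}
ec <- res$encounter_comparison
hi <- ec[ec$risk_level == "high", ]
cat("\nMedian lead time at the high-risk threshold:\n")
for (i in seq_len(nrow(hi))) {
  cat(sprintf("  %-6s %.0f h (IQR %.0f-%.0f)\n", hi$score_name[i],
              hi$median_lead_hours[i], hi$lead_iqr_low[i], hi$lead_iqr_high[i]))
}
cat("\nReport tables written to", out_dir, "\n")
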