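#!/usr/bin/env Rscript
# Step 4 — one-at-a-time weight-sensitivity analysis.
#
# Perturbs each dimension weight over a fine grid (renormalizing the rest
# proportionally), re-evaluates the model, and reports the smallest
# perturbation that flips the optimal strategy — the robustness check the
# additive model calls for.

suppressPackageStartupMessages(library(resilmcda))
dir.create("results", showWarnings = FALSE)

model <- resilience_decision_model()
rep_ <- sensitivity_analysis(model, delta_grid = seq(0.01, 0.99, by = 0.01))
print(rep_)

write.csv(rep_$grid, "results/sensitivity_grid.csv", row.names = FALSE)
jsonlite::write_json(
  list(baseline_optimal = rep_$baseline_optimal,
       min_reversal_delta = as.list(rep_$min_reversal_delta)),
  "results/sensitivity_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)

stable <- names(rep_$min_reversal_delta)[is.na(rep_$min_reversal_delta)]
fragile <- rep_$min_reversal_delta[!is.na(rep_$min_reversal_delta)]
if (length(fragile) > 0) {
  k <- names(fragile)[which.min(fragile)]
  cat("Most sensitive dimension:", k, "- a weight shift of",
      min(fragile), "already flips the optimum.\n")
}
if (length(stable) > 0) {
  cat("No feasible perturbation of", paste(stable, collapse = ", "),
      "reverses the decision within the grid.\n")
}
cat("Wrote results/sensitivity_grid.csv, results/sensitivity_summary.json\n")
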