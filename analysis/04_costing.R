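#!/usr/bin/env Rscript
# Values the estimated activity times with the per-minute salary schedule:
# activity-by-cadre cost matrix with uncertainty intervals, and the
# nurse-base-case visit costs.

suppressMessages(library(prepshift))

fit1 <- fit_from_estimates(
  readr::read_csv("results/fit_model1.csv", show_col_types = FALSE),
  n = nrow(readr::read_csv("results/truth.csv", show_col_types = FALSE)))
sched <- eswatini_salaries()

costs <- cost_matrix(fit1, sched)
readr::write_csv(costs, "results/cost_matrix.csv")

for (vc in c("INITIATION_VISIT", "FOLLOWUP_VISIT")) {
  v <- visit_cost(fit1, "NURSE", sched, visit_class = vc)
  cat(sprintf("%s, all activities by a nurse: $%s [UI %s-%s]\n",
              vc, format_cost(v$point), format_cost(v$ui_low),
              format_cost(v$ui_high)))
}
cat("Wrote results/cost_matrix.csv (",
    nrow(costs), "component-by-cadre cells)\n")
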