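#!/usr/bin/env Rscript
# Evaluates the task-shifting scenario catalogue under the process model:
# per-visit cost ranges with uncertainty intervals, savings against the
# nurse base case, the interruption cost, and freed nurse time.

suppressMessages(library(prepshift))

truth_n <- nrow(readr::read_csv("results/truth.csv", show_col_types = FALSE))
fit2 <- fit_from_estimates(
  readr::read_csv("results/fit_model2.csv", show_col_types = FALSE),
  n = truth_n)
sched <- eswatini_salaries()

tab <- scenario_table(fit2, sched)
readr::write_csv(tab, "results/scenario_table.csv")

ic <- interruption_cost(fit2, sched)
cat(sprintf(
  "Interrupting a workflow adds %.1f min, costing $%s-%s [UI %s-%s]\n",
  ic$minutes, format_cost(ic$cost_low), format_cost(ic$cost_high),
  format_cost(ic$ui_low), format_cost(ic$ui_high)))

for (vc in unique(tab$visit_class)) {
  cat("\n", vc, ":\n", sep = "")
  sub <- tab[tab$visit_class == vc, ]
  for (i in seq_len(nrow(sub))) {
    rng <- if (abs(sub$cost_high[i] - sub$cost_low[i]) < 1e-9) {
      format_cost(sub$cost_low[i])
    } else {
      paste0(format_cost(sub$cost_low[i]), "-", format_cost(sub$cost_high[i]))
    }
    cat(sprintf("  %-11s $%s [UI %s-%s]\n", sub$scenario[i], rng,
                format_cost(sub$ui_low[i]), format_cost(sub$ui_high[i])))
  }
}
cat("\nWrote results/scenario_table.csv\n")
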