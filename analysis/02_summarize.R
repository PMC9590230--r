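#!/usr/bin/env Rscript
# Consolidates the records, builds visit sequences, and tabulates recorded
# HCW time per activity signature (count, mean, range, median, IQR) —
# the descriptive view of how much time PrEP care took.

suppressMessages(library(prepshift))

records <- read_records("results/records.csv", quiet = TRUE)
visits <- suppressWarnings(build_visits(records))
summary_tab <- summarize_sequences(visits)

readr::write_csv(summary_tab, "results/sequence_summary.csv")

cat(nrow(records), "records ->", nrow(visits), "visits (",
    sum(visits$visit_class == "INITIATION_VISIT"), "initiation,",
    sum(visits$visit_class == "FOLLOWUP_VISIT"), "follow-up)\n")
cat("Interrupted:", sum(visits$interrupted), "visits;",
    "multi-HCW:", sum(visits$n_hcws > 1), "\n")
cat(nrow(summary_tab), "distinct activity signatures;",
    "longest mean sequence:",
    round(max(summary_tab$mean), 1), "min\n")
cat("Wrote results/sequence_summary.csv\n")
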