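#!/usr/bin/env Rscript
# Stage 5 — condition comparison.
#
# Assembles the summary table: per-condition contractile pressure, mean
# extrusion-completion time, difference from the control baseline, and a
# one-tailed Student's t-test (significance at P < 0.01) on the completion
# times, testing whether inhibitor-treated extrusion is delayed.

suppressPackageStartupMessages(library(ringforce))

cohort <- read_cohort_table("results/data/cohort.csv")
conditions <- c("control", "Y27632", "blebbistatin")
results <- lapply(conditions, function(cond) {
  entry <- list(
    pressure = read_pressure_result(
      sprintf("results/pressure_%s.json", cond))$pressure)
  v <- cohort$completion_time_s[cohort$condition == cond]
  if (length(v) >= 2L) entry$times <- group_sample(cond, v, "s")
  entry
})
names(results) <- conditions

cmp <- compare_conditions(results, baseline = "control",
                          alternative = "other_greater")
print(cmp)
write_comparison(cmp, "results/comparison")
for (cond in setdiff(conditions, "control")) {
  row <- cmp[cmp$condition == cond, ]
  if (!is.na(row$p_one_tailed))
    message(sprintf("%s: extrusion delayed by %.1f s (one-tailed p = %.2g%s)",
                    cond, row$diff_from_baseline, row$p_one_tailed,
                    if (row$significant) ", significant at P < 0.01" else ""))
}
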