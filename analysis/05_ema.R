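#!/usr/bin/env Rscript
# Step 5 — EMA validation and daily aggregation.
#
# Validates responses against the 6-point (0-5) scale, aggregates to daily
# means per affect item, and produces two-stage group summaries
# (participant means first, then group mean and SD).

suppressMessages(library(greenspaceEMA))

tz <- "America/Los_Angeles"
coh <- read_cohort("results/cohort", tz = tz)

v <- validate_ema(coh$ema)
daily_affect <- daily_mean_affect(v$clean, tz = tz)
gs <- group_summaries(daily_affect, coh$groups)

write.csv(daily_affect, "results/daily_affect.csv", row.names = FALSE)
write.csv(gs, "results/group_summary_affect.csv", row.names = FALSE)

cat(sprintf("%d EMA records (%d rejected) -> %d participant-days\n",
            nrow(v$clean), nrow(v$rejected), nrow(daily_affect)))
for (i in seq_len(nrow(gs)))
  cat(sprintf("  %-12s %-8s %.2f (%.2f)\n", gs$variable[i], gs$group[i],
              gs$mean[i], gs$sd[i]))
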