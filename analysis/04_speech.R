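#!/usr/bin/env Rscript
# Step 4 — speech affect scoring.
#
# Segments the transcripts into social interactions (20-second lapse rule),
# scores each segment against the shipped affect lexicon (category
# percentages of total words), and aggregates to token-weighted daily scores.

suppressMessages(library(greenspaceEMA))

tz <- "America/Los_Angeles"
coh <- read_cohort("results/cohort", tz = tz)
lex <- default_affect_lexicon()

seg <- segment_interactions(coh$transcripts)
seg_scores <- score_segments(seg, lex, tz = tz)
daily_scores <- aggregate_daily_scores(seg_scores)

write.csv(seg_scores, "results/segment_scores.csv", row.names = FALSE)
write.csv(daily_scores, "results/daily_scores.csv", row.names = FALSE)

cat(sprintf("%d utterances -> %d interactions -> %d participant-days\n",
            nrow(coh$transcripts), length(unique(seg$segment)),
            nrow(daily_scores)))
tot <- sum(daily_scores$word_count)
for (k in c("positive", "negative", "anxiety", "anger", "sadness"))
  cat(sprintf("  %-9s %5.2f%% of %d words\n", k,
              100 * sum(daily_scores[[paste0("n_", k)]]) / tot, tot))
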