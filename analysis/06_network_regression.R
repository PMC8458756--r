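#!/usr/bin/env Rscript
# Logistic regression of conscious-pattern (1 and 3) occurrence on each
# network's smoothed activity: 30-frame sliding-mean predictors standardized
# per recording, windows pooled across all recordings, one univariate
# binomial fit per network (alpha = 0.05, uncorrected).
library(brainstates)

out <- file.path("results", "analysis")
states_df <- read.csv(file.path(out, "state_sequences.csv"))
recordings <- load_timecourses(file.path(out, "cohort"))

states <- split(states_df$pattern, states_df$recording)
recordings <- recordings[names(states)]
conditioned <- lapply(recordings, condition_recording)

res <- regress_all_networks(states, conditioned, target_patterns = c(1, 3),
                            window = 30)
write.csv(res, file.path(out, "regression_networks.csv"), row.names = FALSE)

sig <- res[res$significant_positive, ]
cat(sprintf("%d of %d networks have a significant positive slope (p < 0.05):\n",
            nrow(sig), nrow(res)))
print(sig[order(-sig$slope), c("network", "slope", "p_value")], digits = 3)
cat("\ndriven networks in the generator: N06, N20, N21, N30, N40, N41 (+0.5 SD during patterns 1/3)\n")
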