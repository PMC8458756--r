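#!/usr/bin/env Rscript
# Consciousness classification across cohorts: Fisher-score ranking of the
# seven pattern-occupancy features on the 50 anesthesia recordings, a
# linear SVM on the top features, evaluation on the held-out 18 UWS + 20
# control recordings, and the permutation chance level (100 repetitions).
# Also sweeps the number of features from 1 to 7.
library(brainstates)

seed <- 1
out <- file.path("results", "analysis")
states_df <- read.csv(file.path(out, "state_sequences.csv"))
manifest <- jsonlite::read_json(file.path(out, "cohort", "manifest.json"),
                                simplifyVector = TRUE)

states <- split(states_df$pattern, states_df$recording)
idx <- match(names(states), manifest$key)
recs <- lapply(seq_along(states), function(i) {
  time_course_table(matrix(0, 2, 2), tr = manifest$tr[idx[i]],
                    subject = manifest$subject[idx[i]],
                    group = manifest$group[idx[i]],
                    cohort = manifest$cohort[idx[i]])
})
names(recs) <- names(states)

feats <- feature_table(states, recs, k = 7)
train <- feats[feats$cohort == "train", ]
test <- feats[feats$cohort == "test", ]
cat(sprintf("training on %d anesthesia recordings, testing on %d (UWS + controls)\n",
            nrow(train), nrow(test)))

clf <- train_classifier(train, n_features = 2)
cat("Fisher scores (training set):\n")
print(round(sort(clf$scores, decreasing = TRUE), 2))
cat(sprintf("selected features: %s\n", paste(clf$features, collapse = ", ")))

rate <- evaluate_classifier(clf, test)
chance <- permutation_chance(clf, test, n_permutations = 100,
                             seed = derive_seed(seed, "permutation"))
cat(sprintf("correct classification rate: %.3f (chance %.3f +/- %.3f SE)\n",
            rate, chance$mean, chance$se))

sweep <- vapply(1:7, function(nf) {
  m <- suppressWarnings(train_classifier(train, n_features = nf))
  evaluate_classifier(m, test)
}, numeric(1))
cat("rate by number of Fisher-ranked features (1..7):\n")
print(round(sweep, 3))

write.csv(data.frame(n_features = 1:7, rate = sweep),
          file.path(out, "classification_sweep.csv"), row.names = FALSE)
write.csv(data.frame(rate = rate, chance_mean = chance$mean, chance_se = chance$se,
                     n_train = nrow(train), n_test = nrow(test)),
          file.path(out, "classification.csv"), row.names = FALSE)
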