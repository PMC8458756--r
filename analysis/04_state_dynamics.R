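#!/usr/bin/env Rscript
# Occupancy profiles, transition counts and the symmetric transition-
# probability matrix of the fitted state sequences; group comparisons by
# Bonferroni-corrected rank-sum tests (factor 6) and the chi-square test of
# pattern-distribution homogeneity.
library(brainstates)

out <- file.path("results", "analysis")
states_df <- read.csv(file.path(out, "state_sequences.csv"))
manifest <- jsonlite::read_json(file.path(out, "cohort", "manifest.json"),
                                simplifyVector = TRUE)

states <- split(states_df$pattern, states_df$recording)
groups <- manifest$group[match(names(states), manifest$key)]

occ <- occupancy(states, grouping = groups, k = 7)
cat("pooled occupancy by group:\n")
print(round(occ$group[c("AWAKE", "PROP", "SEVO", "UWS"), ], 3))
write.csv(data.frame(group = rownames(occ$group), occ$group, row.names = NULL),
          file.path(out, "occupancy_by_group.csv"), row.names = FALSE)

transitions <- vapply(states, count_transitions, integer(1))
cat("\ntransition counts per recording (mean [range]):\n")
for (g in c("AWAKE", "PROP", "SEVO", "UWS")) {
  v <- transitions[groups == g]
  cat(sprintf("  %-5s %.1f [%d, %d]\n", g, mean(v), min(v), max(v)))
}
ranksum <- compare_groups_ranksum(transitions, groups, bonferroni_factor = 6)
cat("\npairwise rank-sum tests on transition counts (Bonferroni x6):\n")
print(ranksum, digits = 3)
write.csv(ranksum, file.path(out, "ranksum_transitions.csv"), row.names = FALSE)

tmat <- transition_matrix(states, k = 7)
cat("\nsymmetric transition-probability matrix (pooled windows):\n")
print(round(tmat, 4))
write.csv(as.data.frame(tmat), file.path(out, "transition_matrix.csv"))

cat("\nchi-square pattern-distribution tests vs AWAKE:\n")
chi_rows <- lapply(c("PROP", "SEVO", "UWS"), function(g) {
  res <- pattern_distribution_chi2(states[groups == "AWAKE"], states[groups == g])
  cat(sprintf("  AWAKE vs %-4s X2 = %8.1f, df = %d, p %s\n", g, res$statistic,
              res$df, format.pval(res$p_value, eps = 1e-300)))
  data.frame(comparison = paste0("AWAKE_vs_", g), statistic = res$statistic,
             df = res$df, p_value = res$p_value)
})
write.csv(do.call(rbind, chi_rows), file.path(out, "chi2_distribution.csv"),
          row.names = FALSE)
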