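#!/usr/bin/env Rscript
# Group comparison of the AUC metrics (Welch t backed by Mann-Whitney
# and 5000-shuffle permutation tests), Bonferroni-corrected nodal
# tests at the strict (0.05/N) and liberal (1/N) levels, and
# brain-behavior correlations (Pearson + partial controlling for age,
# sex, head motion, duration) within the patient group. Writes the
# statistical tables under results/stats/.

library(fcnet)

data <- read_cohort("results/cohort")
profiles <- readRDS("results/metrics/profiles.rds")
cmp <- compare_groups(profiles, data$clinical, n_perm = 5000, seed = 11L)
write_comparison(cmp, "results/stats")

cat("Global AUC comparisons (patients vs controls):\n")
print(cmp$global[, c("metric", "t", "p_t", "p_mwu", "p_perm",
                     "significant")], row.names = FALSE, digits = 3)
nod <- cmp$nodal
cat(sprintf("\nNodal tests: %d node x metric comparisons; %d strict, %d liberal flags\n",
            nrow(nod), sum(nod$flag_strict), sum(nod$flag_liberal)))
lesion <- nod$node_id <= 20
cat(sprintf("Liberal flags inside the lesioned modules: %d/%d\n",
            sum(nod$flag_liberal & lesion), sum(nod$flag_liberal)))
if (!is.null(cmp$behavior)) {
  cat("\nBrain-behavior correlations within patients:\n")
  print(cmp$behavior, row.names = FALSE, digits = 3)
}
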