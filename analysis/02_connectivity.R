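#!/usr/bin/env Rscript
# Build Fisher-z functional-connectivity matrices for every subject of
# the simulated cohort and check the sparsity band is usable: at the
# lowest threshold the mean degree must exceed ln(N) and the graph
# should not fragment. Writes FC matrices under results/fc/.

library(fcnet)

data <- read_cohort("results/cohort")
vr <- validate_inputs("results/cohort")
stopifnot(vr$n_issues == 0)

dir.create("results/fc", recursive = TRUE, showWarnings = FALSE)
grid <- threshold_grid()
floor_ok <- logical(0)
components <- integer(0)
for (id in names(data$series)) {
  fc <- compute_fc_matrix(list(subject_id = id, data = data$series[[id]]))
  write_fc_matrix(fc, file.path("results/fc", paste0(id, "_fc.tsv")))
  g <- binarize_at_sparsity(fc, min(grid))
  rep <- check_connectedness_floor(g)
  floor_ok <- c(floor_ok, rep$above_floor)
  components <- c(components, rep$n_components)
}
cat("FC matrices written for", length(data$series), "subjects\n")
cat(sprintf("Degree floor at s = %.2f: mean degree > ln(N) for %d/%d subjects\n",
            min(grid), sum(floor_ok), length(floor_ok)))
cat(sprintf("Connected components at the lowest threshold: median %d\n",
            as.integer(median(components))))
# the mean-degree floor 2E/N > ln(N) is an atlas-scale property: at
# N = 264, s = 0.05 gives mean degree 13.2 > ln(264) = 5.6, but at the
# 60-node demonstration scale the same sparsity leaves the graph
# fragmented. The efficiency metrics are robust to this by construction
# (unreachable pairs contribute zero), and Lp flags disconnection.
if (!all(floor_ok))
  cat("Note: the ln(N) floor holds at 264-node atlas scale, not at this\n",
      "demonstration scale; efficiency metrics handle fragmentation.\n")
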