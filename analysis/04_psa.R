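#!/usr/bin/env Rscript
# Step 4: probabilistic sensitivity analysis.
#
# 1000 bootstrap replicates of the cohort with parameter draws from their
# uncertainty distributions, at the 5- and 10-year horizon (NNI 8.3).
# Exports replicate-level outcomes and the ICER-plane data (per occlusion
# stratum without screening costs, pooled with screening costs).

library(ctpcea)

seed <- 2022L
n_reps <- 1000L
cohort <- read_cohort("results/cohort.csv")
params <- load_parameters()

for (h in c(5L, 10L)) {
  p <- params
  p$horizon_years <- h
  psa <- run_psa(cohort, p, n_reps = n_reps, seed = seed)
  cat(sprintf("\nPSA, %d-year horizon, NNI %.1f, %d replicates:\n", h, p$nni, n_reps))
  print(psa$summary, digits = 4, row.names = FALSE)
  cat(sprintf("fraction of replicates cost-effective (NMB > 0): %.3f\n",
              psa$fraction_cost_effective))
  write.csv(psa$replicates, sprintf("results/psa_replicates_%dy.csv", h),
            row.names = FALSE)
  icer <- psa$replicates[, c("rep", "delta_qalys", "delta_costs",
                             grep("_(ICA|M1|M2)$", names(psa$replicates),
                                  value = TRUE))]
  write.csv(icer, sprintf("results/icer_plane_%dy.csv", h), row.names = FALSE)
}

jsonlite::write_json(
  list(step = "04_psa", seed = seed, n_reps = n_reps,
       outputs = sprintf("results/%s_%dy.csv",
                         rep(c("psa_replicates", "icer_plane"), each = 2),
                         c(5L, 10L, 5L, 10L)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
  "results/04_manifest.json", auto_unbox = TRUE)
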