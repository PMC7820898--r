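#!/usr/bin/env Rscript
# Stage 1: generate a synthetic data set with the study's measurement design.
#
# A ground-truth Markov chain of 20 expression states is sampled, 24 cells
# are simulated over 11 hourly time points, and a replicated expression
# table (35-gene panel, 2 biological samples x 2 technical replicates per
# cell and time point, sigma_tech = 0.43 / sigma_bio = 0.1 log2 units) is
# written for the downstream stages. Everything is reproducible from the
# seed below.

suppressPackageStartupMessages(library(plasmonet))

seed <- 20260101L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

chain <- generate_truth_chain(n_states = 20, branching = 1.5,
                              cycle_fraction = 0.2, seed = seed)
traj <- simulate_trajectories(chain, n_cells = 24, n_timepoints = 11,
                              seed = seed + 1L)
panel <- panel_spec()
profiles <- generate_state_profiles(chain, panel, seed = seed + 2L)
expr <- generate_expression_table(traj, panel, profiles, seed = seed + 3L)

write_trajectory_table(traj, file.path(out, "truth_trajectories.tsv"))
write_expression_table(expr, file.path(out, "expression.tsv"))
utils::write.table(
  data.frame(gene = rownames(profiles), profiles, check.names = FALSE),
  file.path(out, "truth_profiles.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("truth chain: %d states, %d edges, %d initial states\n",
            length(chain$states), nrow(chain$edges),
            sum(chain$initial_distribution > 0)))
cat(sprintf("expression table: %d records (%d cells x %d time points x %d genes x 4 replicates)\n",
            nrow(expr), nrow(traj), 11, nrow(panel$genes)))
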