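#!/usr/bin/env Rscript
# Stage 5: visual analytics — classical MDS of the expression patterns and
# discretized per-cell expression kinetics.
#
# MDS embeds every cell-time point by Euclidean distance on log10 expression
# (percent variance per coordinate reported); subsets of the panel (up-,
# down-regulated, pcnA-group) are embedded separately. Kinetics curves show,
# per cell and gene, the log10 ratio of the occupied state's cluster profile
# to the profile at t = 0.

suppressPackageStartupMessages({library(plasmonet); library(dplyr)})

out <- "results/ordination"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

agg <- readr::read_tsv("results/preprocess/aggregated.tsv", show_col_types = FALSE)
mat <- expression_matrix(agg)
panel <- panel_spec()
subsets <- list(
  all = panel$genes$gene,
  up = panel$genes$gene[panel$genes$class == "up"],
  down = panel$genes$gene[panel$genes$class == "down"],
  updown = panel$genes$gene[panel$genes$class %in% c("up", "down")],
  pcna = panel$genes$gene[panel$genes$class == "pcnA_group"])

for (nm in names(subsets)) {
  fit <- classical_mds(mat, k = 2, gene_subset = subsets[[nm]])
  coords <- tibble::tibble(point = rownames(fit$coordinates),
                           dim1 = fit$coordinates[, 1],
                           dim2 = fit$coordinates[, 2])
  readr::write_tsv(coords, file.path(out, sprintf("mds_%s.tsv", nm)))
  cat(sprintf("MDS subset %-7s: %2d genes, variance %.1f%% / %.1f%%\n",
              nm, length(subsets[[nm]]),
              fit$percent_variance[1], fit$percent_variance[2]))
}

prof_tab <- utils::read.delim("results/cluster/cluster_profiles.tsv",
                              check.names = FALSE)
profiles <- as.matrix(prof_tab[, -1])
rownames(profiles) <- prof_tab$gene
traj <- read_trajectory_table("results/cluster/trajectories.tsv")
m <- trajectory_states(traj)
curves <- bind_rows(lapply(seq_len(nrow(m)), function(i) {
  k <- kinetics_curves(m[i, ], profiles)
  k$cell <- traj$cell[i]
  k
}))
readr::write_tsv(curves, file.path(out, "kinetics_curves.tsv"))
cat(sprintf("kinetics: %d curves over %d cells; all anchored at 0 at t=0: %s\n",
            dplyr::n_distinct(curves$gene) * nrow(m), nrow(m),
            all(curves$log10_ratio[curves$time_h == 0] == 0)))
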