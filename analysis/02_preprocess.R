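#!/usr/bin/env Rscript
# Stage 2: normalization and replicate quality control.
#
# Each measurement is normalized to its median over the 35 genes, then each
# gene to its geometric mean over all values. The x-fold deviation of every
# technical replicate from its pair mean summarizes the technical accuracy;
# its quantile table is the synthetic analogue of the reference one (the
# 95th percentile should sit near 1.333 at sigma_tech = 0.43). Discordant
# pairs (two-fold rule) are removed and replicates averaged to one value per
# gene, cell and time point.

suppressPackageStartupMessages(library(plasmonet))

out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression_table("results/synthetic/expression.tsv")
norm <- normalize_gene_geomean(normalize_sample_median(expr))

qc_pair <- replicate_deviations(norm, group = "pair")
qc_quad <- replicate_deviations(norm, group = "quad")
qt <- rbind(
  cbind(group = "pair", deviation_quantiles(qc_pair)),
  cbind(group = "quad", deviation_quantiles(qc_quad)))
readr::write_tsv(qt, file.path(out, "deviation_quantiles.tsv"))

filtered <- apply_qc_filters(norm, qc_pair, fold_limit = 2)
agg <- aggregate_with_fallback(filtered, norm)
readr::write_tsv(agg, file.path(out, "aggregated.tsv"))
cat(sprintf("aggregated matrix complete; %d gene/cell/time combinations refilled from unfiltered means\n",
            attr(agg, "n_refilled")))

cat(sprintf("replicate pairs: %d; 95%% fold deviation: %.3f (median %.3f)\n",
            nrow(qc_pair$deviations) / 2,
            qt$fold_q[qt$group == "pair" & qt$prob == 0.95],
            qt$fold_q[qt$group == "pair" & qt$prob == 0.5]))
cat(sprintf("two-fold rule removed %d of %d measurements; excluded plasmodia: %s\n",
            attr(filtered, "n_removed_measurements"), nrow(norm),
            if (length(attr(filtered, "excluded_plasmodia")) == 0) "none"
            else paste(attr(filtered, "excluded_plasmodia"), collapse = ", ")))
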