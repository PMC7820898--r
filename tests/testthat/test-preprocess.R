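one_measurement <- function(values) {
  make_expr(gene = sprintf("g%d", seq_along(values)), cell = "P1", time_h = 0,
            sample = 1, replicate = 1, value = values)
}

test_that("sample-median normalization rescales each measurement to median 1", {
  expect_equal(normalize_sample_median(one_measurement(c(1, 2, 3)))$value,
               c(0.5, 1, 1.5))
  expect_equal(normalize_sample_median(one_measurement(c(2, 2, 2, 2)))$value,
               rep(1, 4))
  # even count: median is the mean of the two central order statistics
  expect_equal(normalize_sample_median(one_measurement(c(1, 2, 3, 4)))$value,
               c(1, 2, 3, 4) / 2.5)
  # idempotence and ratio preservation
  tab <- one_measurement(c(0.2, 5, 1.7, 9))
  once <- normalize_sample_median(tab)
  expect_equal(normalize_sample_median(once)$value, once$value)
  expect_equal(once$value / once$value[1], tab$value / tab$value[1])
  expect_error(normalize_sample_median(one_measurement(c(1, 0, 2))),
               class = "plasmonet_data_error")
})

test_that("gene geometric-mean normalization and its idempotence", {
  tab <- make_expr(gene = "g1", cell = c("P1", "P2"), time_h = 0,
                   sample = 1, replicate = 1, value = c(1, 4))
  expect_equal(normalize_gene_geomean(tab)$value, c(0.5, 2))
  allc <- make_expr(gene = "g1", cell = sprintf("P%d", 1:3), time_h = 0,
                    sample = 1, replicate = 1, value = rep(7, 3))
  expect_equal(normalize_gene_geomean(allc)$value, rep(1, 3))
  once <- normalize_gene_geomean(tab)
  expect_equal(normalize_gene_geomean(once)$value, once$value)
})

test_that("full normalization of zero-noise data is lossless up to gene and sample scales", {
  chain <- generate_truth_chain(5, seed = 20)
  traj <- simulate_trajectories(chain, 8, 6, seed = 21)
  quiet <- panel_spec(sigma_tech = 0, sigma_bio = 0)
  prof <- generate_state_profiles(chain, quiet, seed = 22)
  tab <- generate_expression_table(traj, quiet, prof, seed = 23, p_fail = 0)
  norm <- normalize_gene_geomean(normalize_sample_median(tab))
  st <- trajectory_states(traj)
  truth <- prof[cbind(
    match(norm$gene, rownames(prof)),
    match(as.character(st[cbind(match(norm$cell, traj$cell), norm$time_h + 1)]),
          colnames(prof)))]
  # log ratio decomposes into a per-gene plus a per-measurement offset
  lr <- log(norm$value / truth)
  fit <- stats::lm(lr ~ factor(norm$gene) +
                     factor(paste(norm$cell, norm$time_h, norm$sample, norm$replicate)))
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
})

test_that("replicate deviations obey r1 + r2 = 2 and flag incomplete groups", {
  pair <- make_expr(gene = "g1", cell = "P1", time_h = 0, sample = 1,
                    replicate = 1:2, value = c(2, 1))
  qc <- replicate_deviations(pair, group = "pair")
  expect_equal(sort(qc$deviations$r), c(2 / 3, 4 / 3))
  same <- make_expr(gene = "g1", cell = "P1", time_h = 0, sample = 1,
                    replicate = 1:2, value = c(5, 5))
  expect_equal(replicate_deviations(same, "pair")$deviations$r, c(1, 1))

  set.seed(30)
  many <- make_expr(gene = "g1", cell = sprintf("P%d", rep(1:50, each = 2)),
                    time_h = 0, sample = 1, replicate = rep(1:2, 50),
                    value = exp(rnorm(100)))
  r <- replicate_deviations(many, "pair")$deviations$r
  expect_equal(as.numeric(tapply(r, rep(1:50, each = 2), sum)), rep(2, 50))

  incomplete <- make_expr(gene = "g1", cell = "P1", time_h = 0, sample = 1,
                          replicate = 1, value = 1)
  expect_error(replicate_deviations(incomplete, "pair"),
               class = "plasmonet_data_error")

  quad <- make_expr(gene = "g1", cell = "P1", time_h = 0,
                    sample = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2),
                    value = c(1, 1, 1, 5))
  expect_equal(sort(replicate_deviations(quad, "quad")$deviations$r),
               c(0.5, 0.5, 0.5, 2.5))
})

test_that("deviation quantiles are monotone with fold = 2^log2", {
  set.seed(31)
  tab <- make_expr(gene = "g1", cell = sprintf("P%d", rep(1:200, each = 2)),
                   time_h = 0, sample = 1, replicate = rep(1:2, 200),
                   value = 2^rnorm(400, 0, 0.4))
  qc <- replicate_deviations(tab, "pair")
  q <- deviation_quantiles(qc)
  expect_identical(nrow(q), 7L)
  expect_true(all(diff(q$log2_q) >= 0))
  expect_equal(q$fold_q, 2^q$log2_q, tolerance = 1e-12)
  expect_equal(q$fold_q[q$prob == 0.5], 1, tolerance = 0.05)

  flat <- make_expr(gene = "g1", cell = c("P1", "P1"), time_h = 0, sample = 1,
                    replicate = 1:2, value = c(3, 3))
  qf <- deviation_quantiles(replicate_deviations(flat, "pair"))
  expect_equal(qf$fold_q, rep(1, 7))
  expect_error(deviation_quantiles(qc, probs = c(0, 0.5)),
               class = "plasmonet_argument_error")
})

test_that("QC filters drop discordant pairs and exclude discordant plasmodia", {
  discordant <- make_expr(gene = "g1", cell = "P1", time_h = 0, sample = 1,
                          replicate = 1:2, value = c(1, 5))
  qc <- replicate_deviations(discordant, "pair")
  expect_identical(nrow(apply_qc_filters(discordant, qc)), 0L)

  fine <- make_expr(gene = "g1", cell = "P1", time_h = 0, sample = 1,
                    replicate = 1:2, value = c(1.5, 1.0))
  expect_identical(nrow(apply_qc_filters(fine, replicate_deviations(fine, "pair"))), 2L)
  expect_error(apply_qc_filters(fine, replicate_deviations(fine, "pair"), fold_limit = 1),
               class = "plasmonet_argument_error")

  # zero-noise synthetic data passes untouched
  chain <- generate_truth_chain(4, seed = 24)
  traj <- simulate_trajectories(chain, 6, 5, seed = 25)
  quiet <- panel_spec(sigma_tech = 0, sigma_bio = 0)
  prof <- generate_state_profiles(chain, quiet, seed = 26)
  tab <- generate_expression_table(traj, quiet, prof, seed = 27, p_fail = 0)
  filt <- apply_qc_filters(tab, replicate_deviations(tab, "pair"))
  expect_identical(nrow(filt), nrow(tab))
  expect_length(attr(filt, "excluded_plasmodia"), 0)

  # a plasmodium whose second sample is 5x off across all genes is excluded
  genes <- sprintf("g%d", 1:5)
  grid <- tidyr::expand_grid(gene = genes, cell = c("A", "B"), time_h = 0L,
                             sample = 1:2, replicate = 1:2)
  grid$value <- ifelse(grid$cell == "A" & grid$sample == 2, 5, 1)
  tab2 <- make_expr(grid$gene, grid$cell, grid$time_h, grid$sample,
                    grid$replicate, grid$value)
  filt2 <- apply_qc_filters(tab2, replicate_deviations(tab2, "pair"))
  expect_identical(attr(filt2, "excluded_plasmodia"), "A")
  expect_setequal(unique(filt2$cell), "B")

  # tightening the limit never retains more records
  set.seed(40)
  noisy <- make_expr(gene = rep(genes, each = 4), cell = "C", time_h = 0,
                     sample = rep(1:2, each = 2, times = 5),
                     replicate = rep(1:2, 10),
                     value = 2^rnorm(20, 0, 0.8))
  qn <- replicate_deviations(noisy, "pair")
  kept <- vapply(c(4, 3, 2, 1.5, 1.2),
                 function(fl) nrow(apply_qc_filters(noisy, qn, fold_limit = fl)),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("aggregation takes the mean of surviving replicate values", {
  four <- make_expr(gene = "g1", cell = "P1", time_h = 0,
                    sample = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2),
                    value = c(1, 2, 3, 4))
  agg <- aggregate_measurements(four)
  expect_equal(agg$value, 2.5)
  expect_identical(agg$n_values, 4L)
  ones <- four; ones$value <- rep(1, 4)
  expect_equal(aggregate_measurements(ones)$value, 1)

  # a discordant pair is dropped, the remaining sample's pair is averaged
  mixed <- make_expr(gene = "g1", cell = "P1", time_h = 0,
                     sample = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2),
                     value = c(1, 5, 2, 2))
  filt <- apply_qc_filters(mixed, replicate_deviations(mixed, "pair"))
  agg2 <- aggregate_measurements(filt)
  expect_equal(agg2$value, 2)
  expect_identical(agg2$n_values, 2L)
})
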