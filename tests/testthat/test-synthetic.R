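test_that("truth chains are valid Markov chains, connected and reproducible", {
  expect_error(generate_truth_chain(0), class = "plasmonet_argument_error")

  single <- generate_truth_chain(1, seed = 1)
  expect_identical(single$states, 1L)
  expect_identical(nrow(single$edges), 0L)
  expect_equal(unname(single$self_stay), 1)

  acyclic <- generate_truth_chain(4, cycle_fraction = 0, seed = 2)
  expect_length(brute_force_cycles(acyclic$edges[, c("from", "to")]), 0)

  expect_identical(generate_truth_chain(10, seed = 1),
                   generate_truth_chain(10, seed = 1))

  for (s in 1:5) {
    ch <- generate_truth_chain(12, branching = 2, cycle_fraction = 0.3, seed = s)
    expect_false(any(ch$edges$from == ch$edges$to))
    expect_true(all(ch$edges$prob >= 0 & ch$edges$prob <= 1))
    row_sums <- ch$self_stay
    for (i in seq_len(nrow(ch$edges))) {
      row_sums[as.character(ch$edges$from[i])] <-
        row_sums[as.character(ch$edges$from[i])] + ch$edges$prob[i]
    }
    expect_equal(unname(row_sums), rep(1, 12), tolerance = 1e-9)
    expect_equal(sum(ch$initial_distribution), 1, tolerance = 1e-12)
    # every state reachable from the initial states
    g <- igraph::graph_from_data_frame(
      ch$edges[, c("from", "to")], directed = TRUE,
      vertices = data.frame(name = ch$states))
    inits <- names(ch$initial_distribution)[ch$initial_distribution > 0]
    reached <- unique(unlist(lapply(inits, function(v)
      names(igraph::subcomponent(g, v, mode = "out")))))
    expect_setequal(reached, as.character(ch$states))
  }
})

test_that("simulated trajectories follow the chain exactly", {
  single <- generate_truth_chain(1, seed = 1)
  traj <- simulate_trajectories(single, 5, 4, seed = 1)
  expect_true(all(trajectory_states(traj) == 1L))

  # forced path a -> b with certainty, no self-stay
  forced <- structure(list(
    states = 1:2,
    edges = tibble::tibble(from = 1L, to = 2L, prob = 1),
    self_stay = c(`1` = 0, `2` = 1),
    initial_distribution = c(`1` = 1, `2` = 0),
    condition = "dark"), class = "truth_chain")
  ft <- trajectory_states(simulate_trajectories(forced, 6, 3, seed = 2))
  expect_true(all(apply(ft, 1, identical, c(t0 = 1L, t1 = 2L, t2 = 2L))))

  chain <- generate_truth_chain(20, seed = 3)
  tab <- simulate_trajectories(chain, 24, 11, seed = 4)
  m <- trajectory_states(tab)
  expect_identical(dim(m), c(24L, 11L))
  # every move is a chain edge; every start has positive initial probability
  edge_keys <- paste(chain$edges$from, chain$edges$to)
  pre <- as.vector(m[, -11]); post <- as.vector(m[, -1])
  moving <- pre != post
  expect_true(all(paste(pre[moving], post[moving]) %in% edge_keys))
  expect_true(all(chain$initial_distribution[as.character(m[, 1])] > 0))
  expect_error(simulate_trajectories(chain, 3, 0), class = "plasmonet_argument_error")
})

test_that("expression generation is exact at zero noise and deterministic", {
  chain <- generate_truth_chain(4, seed = 5)
  traj <- simulate_trajectories(chain, 3, 4, seed = 6)
  quiet <- panel_spec(sigma_tech = 0, sigma_bio = 0)
  prof <- generate_state_profiles(chain, quiet, seed = 7)
  tab <- generate_expression_table(traj, quiet, prof, seed = 8, p_fail = 0)
  st <- trajectory_states(traj)
  expected <- prof[cbind(
    match(tab$gene, rownames(prof)),
    match(as.character(st[cbind(match(tab$cell, traj$cell), tab$time_h + 1)]),
          colnames(prof)))]
  expect_identical(tab$value, unname(expected))
  expect_equal(nrow(tab), 3 * 4 * nrow(quiet$genes) * 4)

  noisy <- panel_spec()
  t1 <- generate_expression_table(traj, noisy, prof, seed = 9)
  t2 <- generate_expression_table(traj, noisy, prof, seed = 9)
  expect_identical(t1, t2)

  bad_prof <- prof[, -1, drop = FALSE]
  expect_error(generate_expression_table(traj, noisy, bad_prof, seed = 1),
               class = "plasmonet_data_error")
})

test_that("replicate deviations of generated data match the closed form and are log-symmetric", {
  chain <- generate_truth_chain(3, seed = 10)
  traj <- simulate_trajectories(chain, 20, 8, seed = 11)
  panel <- panel_spec()  # sigma_tech = 0.43
  prof <- generate_state_profiles(chain, panel, seed = 12)
  tab <- generate_expression_table(traj, panel, prof, seed = 13, p_fail = 0)
  qc <- replicate_deviations(tab, group = "pair")
  q <- deviation_quantiles(qc, probs = c(0.05, 0.5, 0.95))
  # ~22k pairs: compare against the analytic quantiles at a loose MC tolerance
  expect_equal(q$fold_q[3], fold_quantile_closed_form(0.95, 0.43), tolerance = 0.02)
  expect_equal(q$fold_q[1], fold_quantile_closed_form(0.05, 0.43), tolerance = 0.02)
  expect_equal(q$fold_q[2], 1, tolerance = 0.01)
  # symmetry of the log2 deviation distribution
  expect_lt(abs(mean(qc$deviations$log2_r > 0) - 0.5), 0.02)

  # failed-RT-PCR replicates populate a low tail
  low <- generate_expression_table(traj, panel, prof, seed = 13, p_fail = 0.05)
  qlow <- replicate_deviations(low, group = "pair")
  expect_gt(mean(qlow$deviations$log2_r < -2), mean(qc$deviations$log2_r < -2))
})

test_that("the packaged trajectory fixture matches the transcribed reference table", {
  tab <- trajectory_fixture()
  m <- trajectory_states(tab)
  expect_identical(dim(m), c(24L, 11L))
  expect_identical(unname(m["P1", ]), c(60L, 56L, 59L, 26L, 35L, 34L, 34L, 28L, 28L, 32L, 31L))
  expect_identical(unname(m["P24", ]), c(24L, 38L, 45L, 19L, 104L, 108L, 110L, 84L, 81L, 74L, 77L))
  expect_identical(sum(tab$condition == "dark"), 8L)
  expect_identical(sum(tab$condition == "far_red"), 16L)
})
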