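test_that("net construction follows the state-machine building rules", {
  expect_error(build_net(trajectory_fixture()[0, ]), class = "plasmonet_argument_error")

  const <- build_net(make_traj(list(c(5, 5, 5))))
  expect_identical(const$places, 5L)
  expect_identical(sum(!const$transitions$immediate), 0L)
  expect_identical(sum(const$transitions$immediate), 1L)

  example_net <- build_net(make_traj(list(c(1, 2, 3, 3), c(1, 2, 4, 1))))
  ord <- example_net$transitions[!example_net$transitions$immediate, ]
  expect_setequal(paste(ord$pre, ord$post), c("1 2", "2 3", "2 4", "4 1"))
  # free-choice conflict: place 2 has two post-transitions
  expect_identical(sum(ord$pre == 2), 2L)
  expect_identical(sum(example_net$transitions$immediate), 1L)

  net <- build_net(trajectory_fixture())
  expect_identical(length(net$places), 111L)
  expect_identical(sum(!net$transitions$immediate), 159L)
  expect_identical(sum(net$transitions$immediate), 20L)
})

test_that("all constructed nets satisfy the state-machine structural invariants", {
  nets <- list(
    build_net(trajectory_fixture()),
    build_net(make_traj(list(c(1, 2, 3, 3), c(1, 2, 4, 1)))),
    build_net(simulate_trajectories(generate_truth_chain(10, seed = 70), 20, 9, seed = 71))
  )
  for (net in nets) {
    tr <- net$transitions
    expect_true(all(tr$pre != tr$post))
    expect_true(all(tr$pre[tr$immediate] == 0L))
    expect_true(all(tr$pre[!tr$immediate] %in% net$places))
    expect_true(all(tr$post %in% net$places))
    expect_identical(anyDuplicated(paste(tr$pre, tr$post)), 0L)
    expect_false(0L %in% net$places)
  }
})

test_that("annotation counts frequencies, transits and provenance", {
  tab <- trajectory_fixture()
  net <- build_net(tab)
  ann <- net$place_annotations
  expect_equal(ann$relative_frequency[ann$place == 1], 2 / 264)
  expect_equal(sum(ann$relative_frequency), 1)
  ord <- net$transitions[!net$transitions$immediate, ]
  # each of 24 cells contributes 10 transit occurrences, self-transits included
  m <- trajectory_states(tab)
  n_self <- sum(m[, -11] == m[, -1])
  expect_identical(sum(ord$count) + n_self, 240L)
  expect_identical(sum(net$transitions$count[net$transitions$immediate]), 24L)
  # a dark-only transit carries only dark provenance
  prov_60_56 <- ord$provenance[[which(ord$pre == 60 & ord$post == 56)]]
  expect_identical(prov_60_56, "#1/dark")
  mismatched <- make_traj(list(c(999, 998)))
  expect_error(annotate_net(net, mismatched), class = "plasmonet_data_error")
})

test_that("residence stability reflects mean run lengths", {
  tab <- trajectory_fixture()
  net <- residence_stability(build_net(tab), tab)
  ann <- net$place_annotations
  expect_equal(ann$mean_run_length[ann$place == 20], 3)   # P19, t0-t2
  expect_equal(ann$mean_run_length[ann$place == 56], 1)   # only isolated visits
  expect_equal(ann$mean_run_length[ann$place == 60], 4 / 3)  # runs 1, 1 and 2
  expect_true(all(ann$relative_stability > 0 & ann$relative_stability <= 1))
  expect_equal(max(ann$relative_stability), 1)

  const <- make_traj(list(c(5, 5, 5)))
  cn <- residence_stability(build_net(const), const)
  expect_equal(cn$place_annotations$mean_run_length, 3)
})

test_that("graph analysis finds sources, sinks and components", {
  lin <- build_net(make_traj(list(c(1, 2, 3))))
  ga <- graph_analysis(lin)
  expect_identical(ga$sources, 1L)
  expect_identical(ga$sinks, 3L)
  expect_identical(ga$n_weak_components, 1L)

  tab <- trajectory_fixture()
  dark <- tab[tab$condition == "dark", ]
  expect_identical(graph_analysis(build_net(dark))$n_weak_components, 3L)
})

test_that("acceptance of trajectories mirrors net membership", {
  tab <- trajectory_fixture()
  net <- build_net(tab)
  m <- trajectory_states(tab)
  for (i in seq_len(nrow(m))) expect_true(accepts(net, m[i, ]))
  expect_true(accepts(net, c(60, 56, 59)))
  expect_false(accepts(net, c(60, 59, 56)))
  expect_true(accepts(net, integer(0)))
  expect_false(accepts(net, c(999)))
})

test_that("the token game respects the net and its branching statistics", {
  lin <- build_net(make_traj(list(c(1, 2, 3))))
  for (s in 1:5) expect_identical(simulate_token_game(lin, 10, seed = s), c(1L, 2L, 3L))

  branch <- build_net(make_traj(list(c(1, 2), c(1, 3))))
  ends <- vapply(1:10000, function(s) {
    simulate_token_game(branch, 5, seed = s, policy = "uniform")[2]
  }, integer(1))
  expect_lt(abs(mean(ends == 2) - 0.5), 0.02)

  net <- build_net(trajectory_fixture())
  for (s in 1:25) {
    walk <- simulate_token_game(net, 30, seed = s, policy = "weighted")
    expect_true(accepts(net, walk))
    expect_true(all(walk %in% net$places))  # exactly one marked place per step
  }
})

test_that("the reachability graph of the single-token net is isomorphic to its transit graph", {
  for (tabs in list(trajectory_fixture(),
                    make_traj(list(c(1, 2, 3, 3), c(1, 2, 4, 1))))) {
    net <- build_net(tabs)
    rg <- reachability_graph(net)
    ord <- net$transitions[!net$transitions$immediate, ]
    # every place is reachable from the observed initial states, and the
    # marking graph's edges are exactly the net's ordinary transits
    expect_setequal(rg$nodes, net$places)
    expect_setequal(paste(rg$edges$from, rg$edges$to), paste(ord$pre, ord$post))
  }
})

test_that("nets rebuilt from simulated trajectories recover the chain's traversed edges", {
  chain <- generate_truth_chain(12, branching = 2, cycle_fraction = 0.3, seed = 72)
  traj <- simulate_trajectories(chain, 500, 11, seed = 73)
  net <- build_net(traj)
  ord <- net$transitions[!net$transitions$immediate, ]
  chain_edges <- paste(chain$edges$from, chain$edges$to)
  expect_true(all(paste(ord$pre, ord$post) %in% chain_edges))
  # independently count traversed edges from the raw state matrix
  m <- trajectory_states(traj)
  pre <- as.vector(m[, -ncol(m)]); post <- as.vector(m[, -1])
  traversed <- unique(paste(pre[pre != post], post[pre != post]))
  expect_setequal(paste(ord$pre, ord$post), traversed)
  # edges out of the initial states with sizeable probability are all seen
  inits <- as.integer(names(chain$initial_distribution)[chain$initial_distribution > 0])
  likely <- chain$edges[chain$edges$from %in% inits & chain$edges$prob > 0.2, ]
  expect_true(all(paste(likely$from, likely$to) %in% traversed))
})

test_that("net summaries report counts and printed-precision ratios", {
  net <- build_net(trajectory_fixture())
  s <- net_summary(net, n_genes = 35, n_timepoints = 11, n_cells = 24)
  expect_identical(s$n_places, 111L)
  expect_identical(s$n_transitions, 159L)
  expect_equal(s$t_per_p, 159 / 111)
  expect_equal(s$rounded$t_per_p, 1.43)
  expect_equal(s$rounded$p_per_gtc, 0.012)
  expect_error(net_summary(net, 0, 11, 24), class = "plasmonet_argument_error")

  single <- build_net(make_traj(list(c(7, 7))))
  s1 <- net_summary(single, 5, 2, 1)
  expect_identical(s1$n_places, 1L)
  expect_identical(s1$n_transitions, 0L)
  expect_equal(s1$t_per_p, 0)
  expect_identical(s1$n_t_invariants, 0L)
})
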