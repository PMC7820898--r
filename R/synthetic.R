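#' Gene panel specification for the synthetic-data generator
#'
#' Describes the measured gene panel: how many genes are up-regulated,
#' down-regulated, belong to the condition-independent "pcnA-group", or act
#' as unregulated reference genes, together with the regulation span and the
#' multiplicative noise scales of the measurement design. Defaults emulate
#' the 35-gene panel (10 up, 10 down, 4 pcnA-group, 11 reference), a
#' regulation span of ten to more than a hundred fold, and a technical
#' replicate noise of 0.43 log2 units, which places the 95th percentile of
#' the x-fold replicate deviation at 1.333.
#'
#' @param n_up,n_down,n_pcna,n_reference gene counts per class.
#' @param fold_range length-2 numeric, multiplicative span of regulation
#'   (lower bound must exceed 1).
#' @param sigma_tech technical (replicate-level) log2 noise SD.
#' @param sigma_bio biological (sample-level) log2 noise SD.
#' @return an object of class `panel_spec`: a list with a `genes` tibble
#'   (columns `gene`, `class`) and the noise/span parameters.
#' @export
#' @examples
#' panel <- panel_spec()
#' table(panel$genes$class)
panel_spec <- function(n_up = 10, n_down = 10, n_pcna = 4, n_reference = 11,
                       fold_range = c(10, 100),
                       sigma_tech = 0.43, sigma_bio = 0.1) {
  if (fold_range[1] <= 1) abort_arg("fold_range lower bound must exceed 1")
  if (sigma_tech < 0 || sigma_bio < 0) abort_arg("noise SDs must be non-negative")
  genes <- tibble(
    gene = c(sprintf("up%02d", seq_len(n_up)),
             sprintf("dn%02d", seq_len(n_down)),
             sprintf("pcn%02d", seq_len(n_pcna)),
             sprintf("ref%02d", seq_len(n_reference))),
    class = rep(c("up", "down", "pcnA_group", "reference"),
                c(n_up, n_down, n_pcna, n_reference))
  )
  structure(list(genes = genes, fold_range = as.numeric(fold_range),
                 sigma_tech = sigma_tech, sigma_bio = sigma_bio),
            class = "panel_spec")
}

#' Generate a ground-truth Markov chain of expression states
#'
#' Builds a random chain of discrete gene-expression states to act as planted
#' ground truth for pipeline tests. States are arranged along a progression
#' axis; every non-initial state receives one incoming edge from an earlier
#' state so the chain is connected from its initial states, and further edges
#' are added until the mean out-degree reaches `branching`. A fraction
#' `cycle_fraction` of these extra edges is allowed to point backwards,
#' creating cycles; with `cycle_fraction = 0` the chain is acyclic by
#' construction. Self-stays are separate per-state probabilities, not edges.
#'
#' @param n_states number of states (>= 1).
#' @param branching target mean out-degree.
#' @param cycle_fraction proportion of extra edges allowed to point backwards.
#' @param seed integer seed; fixed seed gives an identical chain.
#' @param n_initial number of initial states (default ~ n/5, at least 1).
#' @param condition condition label, `"dark"` or `"far_red"`.
#' @return an object of class `truth_chain`: list with `states` (integer),
#'   `edges` (tibble `from`, `to`, `prob`), `self_stay` (named numeric),
#'   `initial_distribution` (named numeric summing to 1) and `condition`.
#' @export
generate_truth_chain <- function(n_states, branching = 1.5, cycle_fraction = 0.2,
                                 seed = 1, n_initial = max(1L, ceiling(n_states / 5)),
                                 condition = c("far_red", "dark")) {
  condition <- match.arg(condition)
  if (!is.numeric(n_states) || n_states < 1) abort_arg("n_states must be a positive count")
  if (cycle_fraction < 0 || cycle_fraction > 1) abort_arg("cycle_fraction must lie in [0, 1]")
  n_states <- as.integer(n_states)
  states <- seq_len(n_states)
  with_local_seed(seed, {
    initial <- sort(unique(c(1L, if (n_initial > 1L && n_states > 1L)
      sample(states[-1], min(n_initial - 1L, n_states - 1L)))))
    edges <- NULL
    if (n_states > 1L) {
      parent <- vapply(2:n_states, function(j) {
        if (j == 2L) 1L else sample(seq_len(j - 1L), 1L)
      }, integer(1))
      edges <- cbind(from = parent, to = 2:n_states)
      n_extra <- max(0L, round(branching * n_states) - nrow(edges))
      if (n_extra > 0L) {
        backward <- runif(n_extra) < cycle_fraction
        extra <- t(vapply(backward, function(back) {
          repeat {
            pair <- sort(sample(states, 2L))
            e <- if (back) c(pair[2], pair[1]) else pair
            return(e)
          }
        }, integer(2)))
        colnames(extra) <- c("from", "to")
        edges <- rbind(edges, extra)
      }
      edges <- unique(as.data.frame(edges))
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    } else {
      edges <- data.frame(from = integer(0), to = integer(0))
    }
    self_stay <- setNames(rep(1, n_states), states)
    prob <- numeric(nrow(edges))
    for (s in states) {
      idx <- which(edges$from == s)
      if (length(idx) > 0) {
        self_stay[as.character(s)] <- runif(1, 0.3, 0.7)
        w <- rexp(length(idx))
        prob[idx] <- (1 - self_stay[as.character(s)]) * w / sum(w)
      }
    }
    edges$prob <- prob
    init <- setNames(rep(0, n_states), states)
    init[as.character(initial)] <- 1 / length(initial)
    structure(list(states = states,
                   edges = as_tibble(edges),
                   self_stay = self_stay,
                   initial_distribution = init,
                   condition = condition),
              class = "truth_chain")
  })
}

#' Simulate single-cell state trajectories from a truth chain
#'
#' Forward-simulates the Markov chain: each cell starts in a state drawn from
#' the chain's initial distribution and at every sampling interval either
#' stays (self-stay probability) or moves along one of the chain's edges with
#' the edge's probability.
#'
#' @param chain a [generate_truth_chain()] object.
#' @param n_cells number of cells.
#' @param n_timepoints number of time points (>= 1), 1 h spacing.
#' @param seed integer seed.
#' @param experiment experiment batch label.
#' @return a `trajectory_table` (see [read_trajectory_table()] for the
#'   format): one row per cell with state columns `t0` .. `t{K-1}`.
#' @export
simulate_trajectories <- function(chain, n_cells, n_timepoints, seed = 1,
                                  experiment = "1") {
  if (!inherits(chain, "truth_chain") || length(chain$states) == 0) {
    abort_arg("chain must be a non-empty truth_chain")
  }
  if (n_timepoints < 1) abort_arg("n_timepoints must be >= 1")
  n_cells <- as.integer(n_cells); n_timepoints <- as.integer(n_timepoints)
  succ <- split(seq_len(nrow(chain$edges)), chain$edges$from)
  with_local_seed(seed, {
    mat <- matrix(0L, nrow = n_cells, ncol = n_timepoints)
    init_states <- as.integer(names(chain$initial_distribution))
    for (i in seq_len(n_cells)) {
      s <- sample(init_states, 1L, prob = chain$initial_distribution)
      mat[i, 1L] <- s
      if (n_timepoints > 1L) for (t in 2:n_timepoints) {
        idx <- succ[[as.character(s)]]
        if (length(idx) > 0 && runif(1) >= chain$self_stay[as.character(s)]) {
          k <- if (length(idx) == 1L) idx else {
            sample(idx, 1L, prob = chain$edges$prob[idx])
          }
          s <- chain$edges$to[k]
        }
        mat[i, t] <- s
      }
    }
    new_trajectory_table(
      experiment = rep(as.character(experiment), n_cells),
      condition = rep(chain$condition, n_cells),
      cell = sprintf("P%d", seq_len(n_cells)),
      states = mat
    )
  })
}

#' Generate per-state expression profiles for a gene panel
#'
#' Samples one positive expression profile per truth state and gene. Each
#' gene draws a log-uniform baseline and a fold span inside the panel's
#' `fold_range`; up- and down-regulated genes then drift monotonically along
#' the state progression under far-red (flat in the dark), pcnA-group genes
#' perform a condition-independent random walk across states, and reference
#' genes stay at baseline with slight state-to-state jitter.
#'
#' @param chain a [generate_truth_chain()] object.
#' @param panel a [panel_spec()].
#' @param seed integer seed.
#' @return numeric matrix, genes x states (dimnames gene name / state ID);
#'   all entries positive.
#' @export
generate_state_profiles <- function(chain, panel, seed = 1) {
  stopifnot(inherits(panel, "panel_spec"))
  genes <- panel$genes
  n <- length(chain$states)
  prog <- if (n == 1L) 0 else (chain$states - 1) / (n - 1)
  with_local_seed(seed, {
    base <- 10^runif(nrow(genes), -0.5, 0.5)
    span <- exp(runif(nrow(genes), log(panel$fold_range[1]), log(panel$fold_range[2])))
    prof <- matrix(0, nrow = nrow(genes), ncol = n,
                   dimnames = list(genes$gene, chain$states))
    for (i in seq_len(nrow(genes))) {
      prof[i, ] <- switch(
        genes$class[i],
        up = if (chain$condition == "far_red") base[i] * span[i]^prog else
          base[i] * 2^rnorm(n, 0, 0.05),
        down = if (chain$condition == "far_red") base[i] * span[i]^(-prog) else
          base[i] * 2^rnorm(n, 0, 0.05),
        pcnA_group = base[i] * 2^cumsum(rnorm(n, 0, 0.5)),
        reference = base[i] * 2^rnorm(n, 0, 0.05)
      )
    }
    prof
  })
}

#' Generate a replicated expression table from state trajectories
#'
#' Emulates the measurement design: at every cell and time point two
#' biological samples are taken, and each sample is measured twice by
#' multiplex RT-PCR. Each value is the state's profile value perturbed by a
#' sample-level factor `2^N(0, sigma_bio)` and a replicate-level factor
#' `2^N(0, sigma_tech)`. Optionally a small fraction of replicates emulates
#' failed RT-PCR reactions by dropping to `fail_factor` of the expected
#' value (the low tail seen in real deviation histograms).
#'
#' @param trajectories a `trajectory_table`.
#' @param panel a [panel_spec()] providing the noise scales.
#' @param profiles genes x states matrix from [generate_state_profiles()].
#' @param seed integer seed; a fixed seed gives a byte-identical table.
#' @param p_fail probability of a failed-RT-PCR replicate (default 0.01;
#'   set 0 for a clean calibration run).
#' @param fail_factor multiplicative drop applied to failed replicates.
#' @return an `ExpressionTable` tibble with columns `gene`, `cell`,
#'   `experiment`, `condition`, `time_h`, `sample`, `replicate`, `value`.
#' @export
generate_expression_table <- function(trajectories, panel, profiles, seed = 1,
                                      p_fail = 0.01, fail_factor = 0.1) {
  stopifnot(inherits(panel, "panel_spec"))
  states_mat <- trajectory_states(trajectories)
  used <- sort(unique(as.vector(states_mat)))
  missing <- setdiff(as.character(used), colnames(profiles))
  if (length(missing) > 0) {
    abort_data(paste0("no profile for state(s): ", paste(missing, collapse = ", ")))
  }
  if (any(profiles <= 0)) abort_data("all profile values must be positive")
  genes <- rownames(profiles)
  n_tp <- ncol(states_mat)
  long <- tidyr::expand_grid(
    row = seq_len(nrow(states_mat)),
    time_h = seq_len(n_tp) - 1L,
    gene = genes,
    sample = 1:2,
    replicate = 1:2
  )
  long$cell <- trajectories$cell[long$row]
  long$experiment <- trajectories$experiment[long$row]
  long$condition <- trajectories$condition[long$row]
  state <- states_mat[cbind(long$row, long$time_h + 1L)]
  base <- profiles[cbind(match(long$gene, genes), match(as.character(state), colnames(profiles)))]
  with_local_seed(seed, {
    # one biological factor per (cell, time, gene, sample), shared by replicates
    bio_key <- paste(long$row, long$time_h, long$gene, long$sample)
    ubio <- !duplicated(bio_key)
    bio_draw <- setNames(2^rnorm(sum(ubio), 0, panel$sigma_bio), bio_key[ubio])
    tech <- 2^rnorm(nrow(long), 0, panel$sigma_tech)
    value <- base * bio_draw[bio_key] * tech
    if (p_fail > 0) {
      fail <- runif(nrow(long)) < p_fail
      value[fail] <- value[fail] * fail_factor
    }
    out <- tibble(
      gene = long$gene, cell = long$cell, experiment = long$experiment,
      condition = long$condition, time_h = long$time_h,
      sample = long$sample, replicate = long$replicate,
      value = unname(value)
    )
    out[order(out$cell, out$time_h, out$gene, out$sample, out$replicate), ]
  })
}

#' The packaged 24-cell x 11-time-point trajectory fixture
#'
#' Returns the trajectory table of 24 plasmodial cells (P1-P24; 8 dark
#' controls, 16 far-red stimulated; two experiment batches) observed at 11
#' hourly time points, with each state a SIMPROF-significant cluster ID of
#' the reference 35-gene data set. Shipped as a plain-text fixture under
#' `inst/extdata/`.
#'
#' @return a `trajectory_table` with 24 rows and state columns `t0` .. `t10`.
#' @export
#' @examples
#' tab <- trajectory_fixture()
#' nrow(tab)
trajectory_fixture <- function() {
  path <- system.file("extdata", "single_cell_trajectories.tsv", package = "plasmonet")
  if (path == "") abort_data("packaged trajectory fixture not found")
  read_trajectory_table(path)
}

#' Write an expression table to TSV
#' @param table an `ExpressionTable` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  validate_expression_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read an expression table from TSV
#' @param path TSV with header
#'   `gene cell experiment condition time_h sample replicate value`.
#' @return an `ExpressionTable` tibble.
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           gene = "c", cell = "c", experiment = "c",
                           condition = "c", time_h = "i", sample = "i",
                           replicate = "i", value = "d"))
  validate_expression_table(tab)
  tab
}

validate_expression_table <- function(table) {
  needed <- c("gene", "cell", "experiment", "condition", "time_h",
              "sample", "replicate", "value")
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0) {
    abort_data(paste0("expression table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  key <- paste(table$gene, table$cell, table$time_h, table$sample, table$replicate)
  if (anyDuplicated(key) > 0) {
    abort_data("duplicate (gene, cell, time_h, sample, replicate) records")
  }
  invisible(table)
}
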