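#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end run; the effective
#' configuration is persisted as plain text beside the run's outputs so any
#' artifact directory is self-describing.
#'
#' @param seed master seed for every stochastic stage.
#' @param fold_limit QC two-fold rule threshold.
#' @param alpha SIMPROF significance level.
#' @param linkage clustering linkage.
#' @param n_expected,n_simulated SIMPROF permutation counts.
#' @param transform distance transform for clustering and MDS.
#' @param policy token-game firing policy.
#' @param n_states,n_cells,n_timepoints synthetic design (used for
#'   `input = "simulate"`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, fold_limit = 2, alpha = 0.05,
                            linkage = "average", n_expected = 999,
                            n_simulated = 999, transform = "log10",
                            policy = "weighted", n_states = 20,
                            n_cells = 24, n_timepoints = 11) {
  structure(list(seed = seed, fold_limit = fold_limit, alpha = alpha,
                 linkage = linkage, n_expected = n_expected,
                 n_simulated = n_simulated, transform = transform,
                 policy = policy, n_states = n_states, n_cells = n_cells,
                 n_timepoints = n_timepoints),
            class = "pipeline_config")
}

write_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(x) paste(x, collapse = ","), character(1))),
             path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one of three inputs: `"simulate"` (generate a
#' truth chain and a replicated synthetic expression table, then normalize,
#' QC-filter, cluster and build the net), `"fixture"` (build the net
#' directly from the packaged 24-cell trajectory fixture, skipping
#' normalization and clustering), or a `trajectory_table` /
#' `ExpressionTable` object or TSV path. Artifacts (normalized tables, QC
#' quantiles, cluster assignment, trajectory table, ANDL, DOT, summary and
#' annotation TSVs, MDS coordinates, kinetics curves, run log, effective
#' config) are written under `out_dir`; identical config and seed give
#' identical artifacts.
#'
#' @param input see above.
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return invisibly, a list with the main in-memory objects (`trajectories`,
#'   `net`, `summary`, and for expression inputs `matrix`, `assignment`,
#'   `profiles`, `mds`).
#' @export
run_pipeline <- function(input = "simulate", config = pipeline_config(),
                         out_dir = tempfile("plasmonet_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  result <- list()
  n_genes <- NULL
  expr <- NULL
  traj <- NULL

  if (is.character(input) && length(input) == 1 && input == "fixture") {
    traj <- trajectory_fixture()
    n_genes <- 35L
    log_line("stage=input source=fixture cells=%d", nrow(traj))
  } else if (is.character(input) && length(input) == 1 && input == "simulate") {
    chain <- generate_truth_chain(config$n_states, seed = config$seed)
    truth <- simulate_trajectories(chain, config$n_cells, config$n_timepoints,
                                   seed = config$seed + 1)
    panel <- panel_spec()
    profiles <- generate_state_profiles(chain, panel, seed = config$seed + 2)
    expr <- generate_expression_table(truth, panel, profiles,
                                      seed = config$seed + 3, p_fail = 0)
    result$truth_chain <- chain
    result$truth_trajectories <- truth
    write_trajectory_table(truth, file.path(out_dir, "truth_trajectories.tsv"))
    log_line("stage=simulate states=%d cells=%d records=%d",
             config$n_states, config$n_cells, nrow(expr))
  } else if (is.character(input) && length(input) == 1) {
    first <- readLines(input, n = 50)
    if (any(grepl("^experiment\tcondition\tcell", first))) {
      traj <- read_trajectory_table(input)
      n_genes <- 35L
    } else {
      expr <- read_expression_table(input)
    }
    log_line("stage=input source=%s", input)
  } else if (inherits(input, "trajectory_table")) {
    traj <- input
    n_genes <- 35L
  } else {
    expr <- input
    validate_expression_table(expr)
  }

  if (!is.null(expr)) {
    norm <- normalize_gene_geomean(normalize_sample_median(expr))
    qc <- replicate_deviations(norm, group = "pair", fold_limit = config$fold_limit)
    readr::write_tsv(deviation_quantiles(qc), file.path(out_dir, "qc_quantiles.tsv"))
    filtered <- apply_qc_filters(norm, qc, fold_limit = config$fold_limit)
    log_line("stage=qc removed=%d excluded_cells=%s",
             attr(filtered, "n_removed_measurements"),
             paste(attr(filtered, "excluded_plasmodia"), collapse = ",") %||% "none")
    agg <- aggregate_with_fallback(filtered, norm)
    if (attr(agg, "n_refilled") > 0) {
      log_line("stage=aggregate refilled_holes=%d", attr(agg, "n_refilled"))
    }
    mat <- expression_matrix(agg)
    n_genes <- ncol(mat)
    write_expression_table(filtered, file.path(out_dir, "normalized_filtered.tsv"))
    dend <- agglomerate(pairwise_distances(mat, transform = config$transform),
                        linkage = config$linkage)
    assignment <- significant_clusters(dend, mat, alpha = config$alpha,
                                       seed = config$seed + 10,
                                       n_expected = config$n_expected,
                                       n_simulated = config$n_simulated)
    readr::write_tsv(assignment, file.path(out_dir, "cluster_assignment.tsv"))
    log_line("stage=cluster n_clusters=%d", max(assignment$cluster))
    meta <- distinct(expr[, c("cell", "experiment", "condition")])
    traj <- assign_trajectories(assignment, meta)
    profiles <- cluster_profiles(assignment, mat)
    result$matrix <- mat
    result$assignment <- assignment
    result$profiles <- profiles
    mds <- classical_mds(mat, k = 2, transform = config$transform)
    readr::write_tsv(
      dplyr::bind_cols(tibble(point = rownames(mds$coordinates)),
                       as_tibble(mds$coordinates, .name_repair = ~ sprintf(
                         "dim%d_var%.1fpct", seq_along(.x), mds$percent_variance))),
      file.path(out_dir, "mds_coordinates.tsv"))
    result$mds <- mds
    curves <- bind_rows(lapply(seq_len(nrow(traj)), function(i) {
      ki <- kinetics_curves(trajectory_states(traj)[i, ], profiles)
      ki$cell <- traj$cell[i]
      ki
    }))
    readr::write_tsv(curves, file.path(out_dir, "kinetics_curves.tsv"))
  }

  write_trajectory_table(traj, file.path(out_dir, "trajectories.tsv"))
  net <- residence_stability(build_net(traj), traj)
  summary <- net_summary(net, n_genes = n_genes,
                         n_timepoints = ncol(trajectory_states(traj)),
                         n_cells = nrow(traj))
  write_andl(net, file.path(out_dir, "net.andl"))
  write_dot(net, file.path(out_dir, "net.dot"))
  write_net_tables(summary, net, out_dir)
  log_line("stage=net places=%d transitions=%d t_invariants=%d",
           summary$n_places, summary$n_transitions, summary$n_t_invariants)
  write_config(config, file.path(out_dir, "config.txt"))
  result$trajectories <- traj
  result$net <- net
  result$summary <- summary
  result$out_dir <- out_dir
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || !nzchar(a)) b else a
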