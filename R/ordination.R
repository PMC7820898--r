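#' Classical multidimensional scaling of expression patterns
#'
#' Torgerson scaling via [stats::cmdscale]: the squared Euclidean distance
#' matrix is double-centered and eigendecomposed; coordinates are
#' eigenvectors scaled by the square root of the k largest positive
#' eigenvalues, and the percent variance of each coordinate is its
#' eigenvalue over the sum of positive eigenvalues (negative eigenvalues,
#' which arise only for non-Euclidean inputs, are dropped from the
#' denominator). For a deterministic output each coordinate's
#' largest-magnitude loading is made positive.
#'
#' @param matrix cell-time point x gene expression matrix.
#' @param k number of coordinates (>= 1); silently truncated (with a
#'   warning) to the number of positive eigenvalues.
#' @param gene_subset optional character vector of gene (column) names, e.g.
#'   the up-regulated subset; default all columns.
#' @param transform `"log10"` (default) or `"none"` before distances.
#' @return list with `coordinates` (rows as in `matrix`), `eigenvalues` and
#'   `percent_variance` per retained coordinate.
#' @export
classical_mds <- function(matrix, k = 2, gene_subset = NULL,
                          transform = c("log10", "none")) {
  transform <- match.arg(transform)
  if (k < 1) abort_arg("k must be >= 1")
  if (!is.null(gene_subset)) {
    miss <- setdiff(gene_subset, colnames(matrix))
    if (length(miss) > 0) {
      abort_data(paste0("gene subset not in matrix: ", paste(miss, collapse = ", ")))
    }
    if (length(gene_subset) == 0) abort_arg("gene_subset must be non-empty")
    matrix <- matrix[, gene_subset, drop = FALSE]
  }
  d <- pairwise_distances(matrix, transform = transform)
  n <- attr(d, "Size")
  fit <- cmdscale(d, k = min(k, n - 1), eig = TRUE)
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  n_pos <- sum(pos)
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalues; returning %d coordinates",
                    n_pos, n_pos))
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive per coordinate
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  eig <- fit$eig[seq_len(k)]
  list(coordinates = coords,
       eigenvalues = eig,
       percent_variance = 100 * eig / sum(fit$eig[pos]))
}

#' Discretized gene-expression kinetics along a trajectory
#'
#' For each selected gene, the log10 ratio of the cluster profile of the
#' state occupied at time t to the profile of the state occupied at t = 0:
#' `curve(t) = log10(profile[s(t), g]) - log10(profile[s(0), g])`. Every
#' curve starts at exactly 0 and is stepwise constant within residence runs.
#'
#' @param trajectory integer vector of states over time.
#' @param profiles genes x states matrix of (geometric-mean) cluster
#'   profiles, as from [cluster_profiles()] or [generate_state_profiles()].
#' @param genes character vector of genes to plot; default all rows.
#' @return tibble with columns `gene`, `time_h`, `log10_ratio`.
#' @export
kinetics_curves <- function(trajectory, profiles, genes = rownames(profiles)) {
  miss_g <- setdiff(genes, rownames(profiles))
  if (length(miss_g) > 0) {
    abort_data(paste0("genes missing from profiles: ", paste(miss_g, collapse = ", ")))
  }
  miss_s <- setdiff(as.character(trajectory), colnames(profiles))
  if (length(miss_s) > 0) {
    abort_data(paste0("states missing from profiles: ", paste(miss_s, collapse = ", ")))
  }
  p <- log10(profiles[genes, as.character(trajectory), drop = FALSE])
  curves <- p - p[, 1]
  tibble(
    gene = rep(genes, times = length(trajectory)),
    time_h = rep(seq_along(trajectory) - 1, each = length(genes)),
    log10_ratio = as.vector(curves)
  )
}
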