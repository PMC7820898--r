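#' Pairwise Euclidean distances between expression patterns
#'
#' @param matrix numeric matrix, one row per cell-time point, one column per
#'   gene; must be complete.
#' @param transform `"log10"` (default; requires positive values) or
#'   `"none"`.
#' @return a [stats::dist] object.
#' @export
pairwise_distances <- function(matrix, transform = c("log10", "none")) {
  transform <- match.arg(transform)
  if (anyNA(matrix)) {
    holes <- which(is.na(matrix), arr.ind = TRUE)
    abort_data(paste0("missing values at rows: ",
                      paste(unique(rownames(matrix)[holes[, 1]]), collapse = ", ")))
  }
  if (transform == "log10") {
    if (any(matrix <= 0)) abort_data("log10 transform requires positive values")
    matrix <- log10(matrix)
  }
  dist(matrix)
}

#' Agglomerative hierarchical clustering
#'
#' Thin wrapper over [stats::hclust] restricted to the linkages whose merge
#' heights are non-decreasing.
#'
#' @param distances a [stats::dist] object.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an `hclust` merge tree.
#' @export
agglomerate <- function(distances, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  hclust(distances, method = linkage)
}

#' SIMPROF similarity-profile permutation test for one group
#'
#' Tests whether the rows of a candidate group show multivariate structure.
#' The observed profile is the sorted vector of pairwise Euclidean distances
#' between rows. Under the null each variable (column) is permuted
#' independently across rows; the expected profile is the rank-wise mean over
#' `n_expected` such permutations, the statistic is
#' `pi = sum_k |d_(k) - mean expected d_(k)|`, and the p-value is the
#' fraction of `n_simulated` further permuted profiles whose statistic is at
#' least the observed one. Identical rows give `pi = 0` and `p = 1`.
#'
#' @param submatrix numeric matrix with >= 2 rows (the candidate group).
#' @param n_expected,n_simulated permutation counts (defaults 999 each).
#' @param seed integer seed; fixed seed gives a deterministic p-value.
#' @return list with `p_value`, `pi_stat` and `expected_profile`.
#' @export
simprof_pvalue <- function(submatrix, n_expected = 999, n_simulated = 999, seed = 1) {
  submatrix <- as.matrix(submatrix)
  if (nrow(submatrix) < 2) abort_arg("SIMPROF needs at least two rows")
  d_obs <- sort(as.vector(dist(submatrix)))
  # permute each variable across rows; drawing from the sorted column makes
  # the statistic exactly invariant under row reordering of the input
  canon <- apply(submatrix, 2, sort)
  perm_profile <- function(m) {
    pm <- apply(m, 2, function(col) col[sample.int(length(col))])
    sort(as.vector(dist(pm)))
  }
  with_local_seed(seed, {
    prof <- vapply(seq_len(n_expected), function(i) perm_profile(canon),
                   numeric(length(d_obs)))
    expected <- rowMeans(matrix(prof, nrow = length(d_obs)))
    pi_obs <- sum(abs(d_obs - expected))
    pi_sim <- vapply(seq_len(n_simulated), function(i) {
      sum(abs(perm_profile(canon) - expected))
    }, numeric(1))
    list(p_value = mean(pi_sim >= pi_obs), pi_stat = pi_obs,
         expected_profile = expected)
  })
}

#' Discretize expression patterns into SIMPROF-significant clusters
#'
#' Recursively descends the dendrogram from the root: the group at each node
#' is tested with [simprof_pvalue()]; if significant (`p <= alpha`) the
#' recursion continues into the node's children, otherwise the node's leaves
#' form one terminal cluster. Every row is assigned to exactly one cluster.
#' Cluster IDs are contiguous integers ordered by the dendrogram position of
#' each terminal cluster's first leaf, so runs are reproducible.
#'
#' @param dendrogram `hclust` tree from [agglomerate()] built on `matrix`.
#' @param matrix the matrix the tree was built from (rows named
#'   `cell@time_h` where applicable).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed (per-node seeds are derived from it).
#' @param n_expected,n_simulated permutation counts passed through.
#' @return a tibble `cell`, `time_h`, `cluster` (time NA when row names do
#'   not encode a time point), with the test parameters in
#'   `attr(, "parameters")` and per-node p-values in `attr(, "node_tests")`.
#' @export
significant_clusters <- function(dendrogram, matrix, alpha = 0.05, seed = 1,
                                 n_expected = 999, n_simulated = 999) {
  if (alpha <= 0 || alpha >= 1) abort_arg("alpha must lie strictly in (0, 1)")
  n <- nrow(matrix)
  stopifnot(length(dendrogram$order) == n)
  node_leaves <- function(node) {
    if (node < 0) return(-node)
    c(node_leaves(dendrogram$merge[node, 1]),
      node_leaves(dendrogram$merge[node, 2]))
  }
  clusters <- list()
  tests <- list()
  visit <- function(node) {
    leaves <- node_leaves(node)
    if (length(leaves) < 2) {
      clusters[[length(clusters) + 1L]] <<- leaves
      return(invisible())
    }
    node_seed <- (as.integer(seed) + abs(node) * 1000L) %% .Machine$integer.max
    res <- simprof_pvalue(matrix[leaves, , drop = FALSE],
                          n_expected = n_expected, n_simulated = n_simulated,
                          seed = node_seed)
    tests[[length(tests) + 1L]] <<- tibble(node = node, n_leaves = length(leaves),
                                           pi_stat = res$pi_stat,
                                           p_value = res$p_value)
    if (res$p_value <= alpha && node > 0) {
      visit(dendrogram$merge[node, 1])
      visit(dendrogram$merge[node, 2])
    } else {
      clusters[[length(clusters) + 1L]] <<- leaves
    }
    invisible()
  }
  if (n == 1) clusters <- list(1L) else visit(nrow(dendrogram$merge))
  # deterministic IDs: order clusters by first leaf position in the dendrogram
  pos <- match(seq_len(n), dendrogram$order)
  first_pos <- vapply(clusters, function(lv) min(pos[lv]), numeric(1))
  clusters <- clusters[order(first_pos)]
  cluster_of <- integer(n)
  for (k in seq_along(clusters)) cluster_of[clusters[[k]]] <- k
  rn <- rownames(matrix)
  if (is.null(rn)) rn <- as.character(seq_len(n))
  has_time <- grepl("^.+@[0-9.]+$", rn)
  out <- tibble(
    cell = ifelse(has_time, sub("@[0-9.]+$", "", rn), rn),
    time_h = ifelse(has_time, as.numeric(sub("^.*@", "", rn)), NA_real_),
    cluster = cluster_of
  )
  attr(out, "parameters") <- list(alpha = alpha, seed = seed,
                                  n_expected = n_expected,
                                  n_simulated = n_simulated)
  attr(out, "node_tests") <- bind_rows(tests)
  out
}

#' Per-cluster geometric-mean expression profiles
#'
#' @param assignment tibble from [significant_clusters()] (or any tibble
#'   with `cell`, `time_h`, `cluster` matching the matrix rows).
#' @param matrix cell-time point x gene expression matrix with positive
#'   values.
#' @return genes x clusters matrix of geometric means (column names are
#'   cluster IDs) with the member count per cluster in `attr(, "n_members")`.
#' @export
cluster_profiles <- function(assignment, matrix) {
  rn <- ifelse(is.na(assignment$time_h), assignment$cell,
               sprintf("%s@%g", assignment$cell, assignment$time_h))
  idx <- match(rn, rownames(matrix))
  if (anyNA(idx)) abort_data("assignment rows missing from the matrix")
  if (any(matrix[idx, ] <= 0)) abort_data("profiles need positive member values")
  ids <- sort(unique(assignment$cluster))
  prof <- vapply(ids, function(k) {
    members <- idx[assignment$cluster == k]
    exp(colMeans(log(matrix[members, , drop = FALSE])))
  }, numeric(ncol(matrix)))
  prof <- matrix(prof, nrow = ncol(matrix),
                 dimnames = list(colnames(matrix), ids))
  attr(prof, "n_members") <- setNames(
    vapply(ids, function(k) sum(assignment$cluster == k), integer(1)),
    ids)
  prof
}
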