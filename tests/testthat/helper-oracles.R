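# Shared builders and independent oracles used across the suite.

# build a trajectory_table from a list of integer state vectors
make_traj <- function(rows, experiment = "1", condition = "dark",
                      cells = sprintf("P%d", seq_along(rows))) {
  stopifnot(length(unique(lengths(rows))) == 1)
  plasmonet:::new_trajectory_table(
    experiment = rep(experiment, length.out = length(rows)),
    condition = rep(condition, length.out = length(rows)),
    cell = cells,
    states = do.call(rbind, rows)
  )
}

# wrap an edge list (two-column matrix/data.frame, integer node IDs) as a
# state_net so the cycle enumerator can run on arbitrary digraphs
make_net_from_edges <- function(edges, places = NULL) {
  edges <- as.data.frame(edges)
  names(edges) <- c("pre", "post")
  if (is.null(places)) places <- sort(unique(c(edges$pre, edges$post)))
  tr <- tibble::tibble(
    id = sprintf("t%d", seq_len(nrow(edges))),
    pre = as.integer(edges$pre), post = as.integer(edges$post),
    immediate = FALSE, count = 1L, weight = 1,
    provenance = vector("list", nrow(edges)))
  structure(list(places = as.integer(places), transitions = tr,
                 place_annotations = NULL), class = "state_net")
}

# independent brute-force enumeration of elementary directed cycles:
# plain DFS from every vertex over the raw edge list, deduplicated by
# canonical rotation (no SCC restriction, no shared code with the package)
brute_force_cycles <- function(edges) {
  edges <- as.data.frame(edges)
  names(edges) <- c("pre", "post")
  adj <- split(edges$post, edges$pre)
  found <- character(0)
  dfs <- function(start, path) {
    for (w in adj[[as.character(path[length(path)])]]) {
      if (w == start) {
        rot <- which.min(path)
        canon <- paste(c(path[rot:length(path)],
                         if (rot > 1) path[1:(rot - 1)]), collapse = ",")
        found <<- c(found, canon)
      } else if (!(w %in% path)) {
        dfs(start, c(path, w))
      }
    }
  }
  for (v in sort(unique(edges$pre))) dfs(v, v)
  sort(unique(found))
}

canonical_cycles <- function(invariants) {
  sort(vapply(invariants, function(ti) {
    paste(ti$places[-length(ti$places)], collapse = ",")
  }, character(1)))
}

# O(n^3) average-linkage oracle: returns the sorted merge heights
naive_average_linkage_heights <- function(d) {
  D <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(D[clusters[[i]], clusters[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# closed-form quantile of the x-fold deviation of one replicate from the
# pair mean when replicates are c * 2^N(0, sigma^2):
# r = 2 / (1 + 2^d), d ~ N(0, 2 sigma^2), monotone decreasing in d
fold_quantile_closed_form <- function(p, sigma) {
  2 / (1 + 2^(-stats::qnorm(p) * sigma * sqrt(2)))
}

# minimal complete expression table: one value per row spec
make_expr <- function(gene, cell, time_h, sample, replicate, value,
                      experiment = "1", condition = "dark") {
  tibble::tibble(gene = gene, cell = cell, experiment = experiment,
                 condition = condition, time_h = as.integer(time_h),
                 sample = as.integer(sample), replicate = as.integer(replicate),
                 value = value)
}

# two-state partitions agree up to relabeling
partitions_equal <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
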