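#' Build a single-token state-machine Petri net from trajectories
#'
#' Each distinct gene-expression state becomes a place and each distinct
#' ordered pair of consecutive differing states observed in any trajectory
#' becomes one transition (arc weights 1, exactly one pre- and one
#' post-place). Consecutive identical states (self-transits) create no
#' transition; they only contribute to residence time. An auxiliary start
#' place C0 (ID 0) holds the single token initially and is connected by one
#' immediate transition to every distinct initial state, weighted by the
#' number of cells starting there.
#'
#' @param trajectories a `trajectory_table`.
#' @return an object of class `state_net`: list with `places` (integer state
#'   IDs, excluding C0), `transitions` (tibble `id`, `pre`, `post`,
#'   `immediate`, `count`, `weight`, `provenance` list-column) and
#'   `place_annotations` (filled by [annotate_net()] /
#'   [residence_stability()]).
#' @export
build_net <- function(trajectories) {
  if (is.null(trajectories) || nrow(trajectories) == 0) {
    abort_arg("cannot build a net from an empty trajectory table")
  }
  m <- trajectory_states(trajectories)
  places <- sort(unique(as.vector(m)))
  if (any(places <= 0)) abort_data("state IDs must be positive (0 is reserved for C0)")
  pre <- as.vector(m[, -ncol(m), drop = FALSE])
  post <- as.vector(m[, -1, drop = FALSE])
  moving <- pre != post
  pairs <- tibble(pre = pre[moving], post = post[moving]) %>%
    count(.data$pre, .data$post, name = "count") %>%
    arrange(.data$pre, .data$post)
  inits <- tibble(post = m[, 1]) %>% count(.data$post, name = "count") %>%
    arrange(.data$post)
  transitions <- bind_rows(
    tibble(id = sprintf("i%d", seq_len(nrow(inits))), pre = 0L,
           post = inits$post, immediate = TRUE, count = inits$count),
    tibble(id = sprintf("t%d", seq_len(nrow(pairs))), pre = pairs$pre,
           post = pairs$post, immediate = FALSE, count = pairs$count)
  )
  transitions$weight <- as.numeric(transitions$count)
  transitions$provenance <- vector("list", nrow(transitions))
  net <- structure(list(places = places, transitions = transitions,
                        place_annotations = NULL),
                   class = "state_net")
  annotate_net(net, trajectories)
}

#' @export
print.state_net <- function(x, ...) {
  ord <- !x$transitions$immediate
  cat(sprintf("state-machine Petri net: %d places (+C0), %d transitions, %d immediate\n",
              length(x$places), sum(ord), sum(!ord)))
  invisible(x)
}

#' Annotate a net with state frequencies and transit provenance
#'
#' Computes, from the trajectories the net was built from: the relative
#' frequency of every place (occurrences of its state over all cell-time
#' points), the occurrence count of every transit, and the set of
#' (experiment, condition) labels of the cells exhibiting each transit.
#'
#' @param net a `state_net`.
#' @param trajectories the `trajectory_table` the net was built from.
#' @return the annotated `state_net`.
#' @export
annotate_net <- function(net, trajectories) {
  m <- trajectory_states(trajectories)
  if (!all(unique(as.vector(m)) %in% net$places)) {
    abort_data("trajectories contain states that are not places of the net")
  }
  occ <- table(factor(as.vector(m), levels = net$places))
  k <- ncol(m)
  lab <- sprintf("#%s/%s", trajectories$experiment, trajectories$condition)
  pre <- as.vector(m[, -k, drop = FALSE]); post <- as.vector(m[, -1, drop = FALSE])
  row_of <- rep(seq_len(nrow(m)), k - 1L)
  moving <- pre != post
  edge_key <- paste(pre[moving], post[moving])
  prov_by_edge <- split(lab[row_of[moving]], edge_key)
  cnt_by_edge <- lengths(split(row_of[moving], edge_key))
  init_key <- paste(0L, m[, 1])
  prov_by_edge <- c(prov_by_edge, split(lab, init_key))
  cnt_by_edge <- c(cnt_by_edge, lengths(split(seq_len(nrow(m)), init_key)))
  tk <- paste(net$transitions$pre, net$transitions$post)
  if (!all(tk %in% names(cnt_by_edge))) {
    abort_data("net contains transitions never observed in the trajectories")
  }
  net$transitions$count <- as.integer(cnt_by_edge[tk])
  net$transitions$weight <- as.numeric(net$transitions$count)
  net$transitions$provenance <- lapply(prov_by_edge[tk], function(x) sort(unique(x)))
  ann <- tibble(place = net$places,
                relative_frequency = as.numeric(occ) / length(m))
  ga <- graph_analysis(structure(list(places = net$places,
                                      transitions = net$transitions),
                                 class = "state_net"))
  ann$is_source <- ann$place %in% ga$sources
  ann$is_sink <- ann$place %in% ga$sinks
  prev <- net$place_annotations
  if (!is.null(prev) && "mean_run_length" %in% names(prev)) {
    ann <- left_join(ann, prev[, c("place", "mean_run_length", "relative_stability")],
                     by = "place")
  }
  net$place_annotations <- ann
  net
}

#' Relative temporal stability of expression states
#'
#' For each state, the mean length (in sampling intervals) of the maximal
#' runs of consecutive occupancy across all trajectories; runs truncated by
#' the start or end of a series count at their observed length. The relative
#' stability is the mean run length divided by the maximum mean run length
#' over all states, so it lies in (0, 1].
#'
#' @param net a `state_net`.
#' @param trajectories the table the net was built from.
#' @return the net with `mean_run_length` and `relative_stability` added to
#'   `place_annotations`.
#' @export
residence_stability <- function(net, trajectories) {
  m <- trajectory_states(trajectories)
  runs <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    r <- rle(m[i, ])
    data.frame(place = r$values, len = r$lengths)
  }))
  if (!all(net$places %in% runs$place)) {
    abort_data("net contains places absent from the trajectories")
  }
  mean_len <- tapply(runs$len, factor(runs$place, levels = net$places), mean)
  rel <- as.numeric(mean_len) / max(mean_len)
  ann <- net$place_annotations
  ann$mean_run_length <- as.numeric(mean_len)
  ann$relative_stability <- rel
  net$place_annotations <- ann
  net
}

ordinary_graph <- function(net) {
  tr <- net$transitions[!net$transitions$immediate, ]
  igraph::graph_from_data_frame(
    data.frame(from = as.character(tr$pre), to = as.character(tr$post)),
    directed = TRUE, vertices = data.frame(name = as.character(net$places)))
}

#' Sources, sinks and connected components of a net
#'
#' Computed on the ordinary-transition graph, excluding C0 and its immediate
#' transitions: sinks are places with no outgoing transition (terminal
#' expression states), sources are places with no incoming ordinary
#' transition.
#'
#' @param net a `state_net`.
#' @return list with `sources`, `sinks` (integer place IDs),
#'   `weak_components` / `strong_components` (named membership vectors) and
#'   `n_weak_components` / `n_strong_components`.
#' @export
graph_analysis <- function(net) {
  g <- ordinary_graph(net)
  outd <- igraph::degree(g, mode = "out")
  ind <- igraph::degree(g, mode = "in")
  wc <- igraph::components(g, mode = "weak")
  sc <- igraph::components(g, mode = "strong")
  list(
    sources = sort(as.integer(names(ind)[ind == 0])),
    sinks = sort(as.integer(names(outd)[outd == 0])),
    weak_components = setNames(wc$membership, igraph::V(g)$name),
    n_weak_components = as.integer(wc$no),
    strong_components = setNames(sc$membership, igraph::V(g)$name),
    n_strong_components = as.integer(sc$no)
  )
}

#' Enumerate minimal T-invariants (elementary cycles)
#'
#' In a state machine every elementary directed cycle of the place/transit
#' graph is a minimal T-invariant: firing its transitions once returns the
#' single token to the place it started from. Cycles are enumerated on the
#' ordinary-transition graph (C0 and immediate transitions excluded) by
#' backtracking restricted to nontrivial strongly connected components,
#' rooted at each component's smallest place so every cycle is found exactly
#' once in canonical rotation (smallest place ID first). The result is
#' sorted by cycle length, then lexicographically by place sequence.
#'
#' @param net a `state_net`.
#' @param max_cycles enumeration cap; exceeding it raises an error.
#' @return list of `t_invariant` objects, each a list with `places` (the
#'   cycle's place sequence, first place repeated at the end) and
#'   `transitions` (the transition IDs fired, in order).
#' @export
minimal_t_invariants <- function(net, max_cycles = 1e6) {
  tr <- net$transitions[!net$transitions$immediate, ]
  if (nrow(tr) == 0) return(list())
  g <- ordinary_graph(net)
  scc <- igraph::components(g, mode = "strong")$membership
  adj <- split(tr$post, tr$pre)
  tid <- setNames(tr$id, paste(tr$pre, tr$post))
  cycles <- list()
  n_found <- 0L
  for (comp in unique(scc[scc %in% scc[duplicated(scc)]])) {
    members <- sort(as.integer(names(scc)[scc == comp]))
    for (root in members) {
      # elementary paths from root through vertices > root (within the SCC)
      path <- root
      search <- function() {
        v <- path[length(path)]
        for (w in sort(adj[[as.character(v)]])) {
          if (w == root) {
            n_found <<- n_found + 1L
            if (n_found > max_cycles) {
              abort(sprintf("cycle enumeration exceeded cap of %g", max_cycles),
                    class = "plasmonet_bounded_enumeration_error")
            }
            cyc <- c(path, root)
            cycles[[n_found]] <<- structure(
              list(places = cyc,
                   transitions = unname(tid[paste(head(cyc, -1), cyc[-1])])),
              class = "t_invariant")
          } else if (w > root && !(w %in% path) &&
                       !is.na(scc[as.character(w)]) &&
                       scc[as.character(w)] == comp) {
            path <<- c(path, w)
            search()
            path <<- head(path, -1)
          }
        }
      }
      search()
    }
  }
  keys <- vapply(cycles, function(cy) {
    sprintf("%04d|%s", length(cy$places), paste(sprintf("%06d", cy$places), collapse = ","))
  }, character(1))
  cycles[order(keys)]
}

#' Summary metrics of a net
#'
#' Counts of places, transitions (both excluding C0 and immediates) and
#' minimal T-invariants, with the derived ratios per gene, per place and per
#' measured cell-time point, reported unrounded and at the customary printed
#' precisions (1, 1, 2, 3 and 3 decimals).
#'
#' @param net a `state_net`.
#' @param n_genes,n_timepoints,n_cells the design the trajectories came from.
#' @return list of counts and ratios (`rounded` holds the printed-precision
#'   versions).
#' @export
net_summary <- function(net, n_genes, n_timepoints, n_cells) {
  if (n_genes <= 0 || n_timepoints <= 0 || n_cells <= 0) {
    abort_arg("n_genes, n_timepoints, n_cells must be positive")
  }
  n_p <- length(net$places)
  n_t <- sum(!net$transitions$immediate)
  tinv <- minimal_t_invariants(net)
  ga <- graph_analysis(net)
  denom <- n_genes * n_timepoints * n_cells
  out <- list(
    n_places = n_p, n_transitions = n_t, n_t_invariants = length(tinv),
    n_genes = n_genes, n_timepoints = n_timepoints, n_cells = n_cells,
    p_per_gene = n_p / n_genes, t_per_gene = n_t / n_genes,
    t_per_p = if (n_p > 0) n_t / n_p else 0,
    p_per_gtc = n_p / denom, t_per_gtc = n_t / denom,
    tinv_per_gene = length(tinv) / n_genes,
    n_sources = length(ga$sources), n_sinks = length(ga$sinks),
    n_components = ga$n_weak_components
  )
  out$rounded <- list(
    p_per_gene = round(out$p_per_gene, 1), t_per_gene = round(out$t_per_gene, 1),
    t_per_p = round(out$t_per_p, 2), p_per_gtc = round(out$p_per_gtc, 3),
    t_per_gtc = round(out$t_per_gtc, 3))
  out
}

#' Does a net accept a trajectory?
#'
#' A state machine with one token is isomorphic to its reachability graph,
#' so a state sequence is feasible exactly when its initial state is served
#' by an immediate transition from C0 and every consecutive pair of
#' differing states is an ordinary transition of the net. The empty
#' trajectory is vacuously accepted.
#'
#' @param net a `state_net`.
#' @param trajectory integer vector of states.
#' @return `TRUE` or `FALSE`.
#' @export
accepts <- function(net, trajectory) {
  if (length(trajectory) == 0) return(TRUE)
  tr <- net$transitions
  if (!trajectory[1] %in% tr$post[tr$immediate]) return(FALSE)
  if (length(trajectory) == 1) return(TRUE)
  pre <- trajectory[-length(trajectory)]; post <- trajectory[-1]
  moving <- pre != post
  edge <- paste(tr$pre[!tr$immediate], tr$post[!tr$immediate])
  all(paste(pre[moving], post[moving]) %in% edge)
}

#' Play the token game
#'
#' Simulates the net as the Markov chain it is isomorphic to: one immediate
#' transition fires first (probability proportional to the number of cells
#' starting in each initial state, or uniform), then at every step one
#' enabled post-transition of the token's place fires (uniform, or
#' proportional to observed transit counts under `"weighted"`). The walk
#' stops at a sink place or after `n_steps` ordinary firings; exactly one
#' token exists throughout.
#'
#' @param net a `state_net`.
#' @param n_steps maximum number of ordinary firings.
#' @param seed integer seed.
#' @param policy `"uniform"` or `"weighted"`.
#' @return integer vector of visited states (starting with the initial one).
#' @export
simulate_token_game <- function(net, n_steps, seed = 1,
                                policy = c("uniform", "weighted")) {
  policy <- match.arg(policy)
  tr <- net$transitions
  imm <- tr[tr$immediate, ]
  ord <- tr[!tr$immediate, ]
  succ <- split(seq_len(nrow(ord)), ord$pre)
  with_local_seed(seed, {
    p0 <- if (policy == "weighted") imm$weight else rep(1, nrow(imm))
    s <- imm$post[sample.int(nrow(imm), 1L, prob = p0)]
    seqv <- s
    steps <- 0L
    while (steps < n_steps) {
      idx <- succ[[as.character(s)]]
      if (is.null(idx) || length(idx) == 0) break
      pw <- if (policy == "weighted") ord$weight[idx] else rep(1, length(idx))
      k <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L, prob = pw)]
      s <- ord$post[k]
      seqv <- c(seqv, s)
      steps <- steps + 1L
    }
    seqv
  })
}

#' Structural equality of two nets
#' @param a,b `state_net` objects.
#' @return `TRUE` when places and (pre, post, immediate, weight) transition
#'   sets coincide.
#' @export
net_equal <- function(a, b) {
  key <- function(n) {
    tr <- n$transitions[order(n$transitions$pre, n$transitions$post), ]
    list(places = sort(n$places),
         edges = paste(tr$pre, tr$post, tr$immediate, tr$weight))
  }
  identical(key(a)$places, key(b)$places) && identical(key(a)$edges, key(b)$edges)
}

#' Reachability graph of the single-token net
#'
#' Explicitly constructs the graph of reachable markings (each marking has
#' the token on exactly one place) from the markings put by C0's immediate
#' transitions, following ordinary transitions. For a state machine this
#' graph has the same edges as the net's own place/transit graph restricted
#' to places reachable from the initial states.
#'
#' @param net a `state_net`.
#' @return list with `nodes` (place IDs = markings) and `edges`
#'   (tibble `from`, `to`).
#' @export
reachability_graph <- function(net) {
  tr <- net$transitions
  ord <- tr[!tr$immediate, ]
  frontier <- unique(tr$post[tr$immediate])
  seen <- frontier
  edges <- list()
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (s in frontier) {
      to <- ord$post[ord$pre == s]
      if (length(to) > 0) {
        edges[[length(edges) + 1L]] <- tibble(from = s, to = to)
        nxt <- c(nxt, setdiff(to, seen))
      }
    }
    frontier <- unique(nxt)
    seen <- union(seen, frontier)
  }
  list(nodes = sort(seen),
       edges = if (length(edges) > 0) distinct(bind_rows(edges)) else
         tibble(from = integer(0), to = integer(0)))
}
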