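#' Trajectory tables
#'
#' A `trajectory_table` is a tibble with one row per cell: metadata columns
#' `experiment`, `condition`, `cell` followed by integer state columns
#' `t0`, `t1`, ... on a uniform 1 h grid. Each state is a cluster ID
#' (a significant gene-expression state).
#'
#' @param experiment,condition,cell character vectors, one entry per cell.
#' @param states integer matrix, cells x time points.
#' @return a `trajectory_table`.
#' @keywords internal
new_trajectory_table <- function(experiment, condition, cell, states) {
  states <- matrix(as.integer(states), nrow = length(cell))
  colnames(states) <- sprintf("t%d", seq_len(ncol(states)) - 1L)
  out <- dplyr::bind_cols(
    tibble(experiment = experiment, condition = condition, cell = cell),
    as_tibble(states)
  )
  class(out) <- c("trajectory_table", class(out))
  out
}

#' Extract the state matrix of a trajectory table
#' @param table a `trajectory_table`.
#' @return integer matrix cells x time points, rownames = cell IDs.
#' @export
trajectory_states <- function(table) {
  tcols <- grep("^t[0-9]+$", names(table), value = TRUE)
  m <- as.matrix(table[, tcols])
  storage.mode(m) <- "integer"
  rownames(m) <- table$cell
  m
}

#' Assemble per-cell state trajectories from a cluster assignment
#'
#' Orders each cell's cluster IDs by time to give its temporal sequence of
#' gene-expression states, one row per cell.
#'
#' @param assignment tibble with columns `cell`, `time_h`, `cluster`
#'   (as produced by [significant_clusters()]).
#' @param metadata tibble with columns `cell`, `experiment`, `condition`.
#' @return a `trajectory_table`.
#' @export
assign_trajectories <- function(assignment, metadata) {
  cells <- unique(metadata$cell)
  times <- sort(unique(assignment$time_h))
  grid <- tidyr::expand_grid(cell = cells, time_h = times)
  merged <- left_join(grid, assignment, by = c("cell", "time_h"))
  if (anyNA(merged$cluster)) {
    holes <- merged[is.na(merged$cluster), c("cell", "time_h")]
    abort_data(paste0("missing cluster assignment for: ",
                      paste(sprintf("%s@%sh", holes$cell, holes$time_h), collapse = ", ")))
  }
  mat <- matrix(merged$cluster, nrow = length(cells), byrow = TRUE,
                dimnames = list(cells, NULL))
  meta <- metadata[match(cells, metadata$cell), ]
  new_trajectory_table(meta$experiment, meta$condition, cells, mat)
}

#' Read a trajectory table from TSV
#'
#' Expects a tab-separated file with header
#' `experiment condition cell t0 t1 ...`; lines starting with `#` are
#' comments. All rows must have the same number of integer state columns.
#'
#' @param path input file.
#' @return a `trajectory_table`.
#' @export
read_trajectory_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) abort_data("trajectory file has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  tcols <- grep("^t[0-9]+$", header)
  need <- c("experiment", "condition", "cell")
  if (!all(need %in% header) || length(tcols) < 1) {
    abort_data("trajectory header must contain experiment, condition, cell, t0..")
  }
  n_col <- length(header)
  rows <- fields[-1]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_col) {
      abort_data(sprintf("line %d: expected %d fields, found %d",
                         lineno[i + 1L], n_col, length(rows[[i]])))
    }
    sv <- rows[[i]][tcols]
    if (anyNA(suppressWarnings(as.integer(sv))) ||
        any(as.numeric(sv) != as.integer(sv))) {
      abort_data(sprintf("line %d: non-integer state value", lineno[i + 1L]))
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- header
  states <- matrix(as.integer(m[, tcols, drop = FALSE]), nrow = nrow(m))
  tab <- new_trajectory_table(m[, "experiment"], m[, "condition"], m[, "cell"], states)
  if (anyDuplicated(paste(tab$experiment, tab$cell)) > 0) {
    abort_data("duplicate (experiment, cell) rows")
  }
  tab
}

#' Write a trajectory table to TSV
#' @param table a `trajectory_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}
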