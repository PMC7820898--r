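#' Export a net as ANDL or DOT
#'
#' ANDL (Abstract Net Description Language) output is one stochastic
#' Petri-net block listing every place with its initial marking (C0 = 1, all
#' gene-expression places 0) and every transition with its single pre-arc
#' and post-arc (arc weight 1), its firing weight and an `immediate` flag.
#' The exact grammar the writer emits and the reader parses is documented in
#' `inst/ANDL-grammar.md`; `read_andl(write_andl(net))` reproduces the net
#' structurally. DOT output is a bipartite digraph (places as circles,
#' transitions as boxes) with the annotations (relative frequency,
#' stability, provenance) emitted as node attributes.
#'
#' @param net a `state_net`.
#' @param format `"andl"` or `"dot"`.
#' @param path output file.
#' @param name net name used in the file header.
#' @return `path`, invisibly.
#' @export
export_net <- function(net, format = c("andl", "dot"), path, name = "waddington_net") {
  format <- match.arg(format)
  switch(format,
         andl = write_andl(net, path, name = name),
         dot = write_dot(net, path, name = name))
}

#' @rdname export_net
#' @export
write_andl <- function(net, path, name = "waddington_net") {
  tr <- net$transitions[order(net$transitions$immediate == FALSE,
                              net$transitions$pre, net$transitions$post), ]
  lines <- c(
    sprintf("spn [%s]", name),
    "{",
    "places:",
    "  C0 = 1;",
    sprintf("  C%d = 0;", net$places),
    "transitions:",
    sprintf("  %s%s: C%d -> C%d : %s;",
            tr$id, ifelse(tr$immediate, " immediate", ""),
            tr$pre, tr$post, format(tr$weight, trim = TRUE, scientific = FALSE)),
    "}"
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a net from the package's ANDL dialect
#'
#' @param path ANDL file written by [write_andl()].
#' @return a `state_net` (without trajectory-derived annotations).
#' @export
read_andl <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !grepl("^//", lines)]
  sec <- NA_character_
  places <- integer(0)
  marking <- integer(0)
  trs <- list()
  for (ln in lines) {
    if (grepl("^spn\\b", ln) || ln %in% c("{", "}")) next
    if (grepl("^places:", ln)) { sec <- "places"; next }
    if (grepl("^transitions:", ln)) { sec <- "transitions"; next }
    if (is.na(sec)) abort_data(paste0("ANDL content outside any section: ", ln))
    if (sec == "places") {
      m <- regmatches(ln, regexec("^C([0-9]+)\\s*=\\s*([0-9]+);$", ln))[[1]]
      if (length(m) == 0) abort_data(paste0("bad ANDL place line: ", ln))
      places <- c(places, as.integer(m[2])); marking <- c(marking, as.integer(m[3]))
    } else {
      m <- regmatches(ln, regexec(
        "^([A-Za-z0-9_]+)( immediate)?:\\s*C([0-9]+)\\s*->\\s*C([0-9]+)\\s*:\\s*([0-9.eE+-]+);$",
        ln))[[1]]
      if (length(m) == 0) abort_data(paste0("bad ANDL transition line: ", ln))
      trs[[length(trs) + 1L]] <- tibble(
        id = m[2], immediate = nzchar(m[3]),
        pre = as.integer(m[4]), post = as.integer(m[5]),
        weight = as.numeric(m[6]))
    }
  }
  if (!0L %in% places || marking[places == 0L] != 1L || any(marking[places != 0L] != 0L)) {
    abort_data("ANDL net must mark C0 with the single token")
  }
  tr <- bind_rows(trs)
  tr$count <- as.integer(round(tr$weight))
  tr$provenance <- vector("list", nrow(tr))
  tr <- tr[, c("id", "pre", "post", "immediate", "count", "weight", "provenance")]
  structure(list(places = sort(setdiff(places, 0L)), transitions = tr,
                 place_annotations = NULL),
            class = "state_net")
}

#' @rdname export_net
#' @export
write_dot <- function(net, path, name = "waddington_net") {
  ann <- net$place_annotations
  place_attr <- vapply(net$places, function(p) {
    extra <- ""
    if (!is.null(ann)) {
      row <- ann[ann$place == p, ]
      if (nrow(row) == 1) {
        extra <- sprintf(", frequency=\"%.6f\"%s%s",
                         row$relative_frequency,
                         if (!is.null(row$relative_stability) &&
                               !is.na(row$relative_stability))
                           sprintf(", stability=\"%.6f\"", row$relative_stability) else "",
                         if (isTRUE(row$is_sink)) ", sink=\"true\"" else "")
      }
    }
    sprintf("  C%d [shape=circle%s];", p, extra)
  }, character(1))
  tr <- net$transitions
  prov <- vapply(tr$provenance, function(p) {
    if (is.null(p) || length(p) == 0) "" else
      sprintf(", provenance=\"%s\"", paste(p, collapse = ";"))
  }, character(1))
  tr_nodes <- sprintf("  %s [shape=box, label=\"%s\", count=\"%d\"%s%s];",
                      tr$id, tr$id, tr$count,
                      ifelse(tr$immediate, ", style=filled, fillcolor=black", ""),
                      prov)
  arcs <- c(sprintf("  C%d -> %s;", tr$pre, tr$id),
            sprintf("  %s -> C%d;", tr$id, tr$post))
  lines <- c(sprintf("digraph %s {", name),
             "  rankdir=TB;",
             "  C0 [shape=circle, label=\"C0\"];",
             place_attr, tr_nodes, arcs, "}")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write the summary metrics and the place/transition annotations as TSV
#'
#' @param summary a [net_summary()] result.
#' @param net an annotated `state_net`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_net_tables <- function(summary, net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- tibble(
    metric = c("Places", "Transitions", "P/Gene", "T/Gene", "Time points",
               "Cells", "P/(Genes x tps x cells)", "T/(Genes x tps x cells)",
               "T/P", "T-Inv", "T-Inv/Gene", "Sources", "Sinks", "Components"),
    value = c(summary$n_places, summary$n_transitions,
              summary$rounded$p_per_gene, summary$rounded$t_per_gene,
              summary$n_timepoints, summary$n_cells,
              summary$rounded$p_per_gtc, summary$rounded$t_per_gtc,
              summary$rounded$t_per_p, summary$n_t_invariants,
              round(summary$tinv_per_gene, 2), summary$n_sources,
              summary$n_sinks, summary$n_components))
  readr::write_tsv(rows, file.path(dir, "net_summary.tsv"))
  readr::write_tsv(net$place_annotations, file.path(dir, "place_annotations.tsv"))
  tr <- net$transitions
  tr$provenance <- vapply(tr$provenance, function(p) paste(p, collapse = ";"),
                          character(1))
  readr::write_tsv(tr, file.path(dir, "transitions.tsv"))
  invisible(dir)
}
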