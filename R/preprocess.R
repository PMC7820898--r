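#' Normalize each measurement to its median over genes
#'
#' Corrects for differences in total RNA amount and RT-PCR efficiency: within
#' every single measurement (one cell, time point, biological sample and
#' technical replicate) each gene's value is divided by the median of all
#' gene values of that measurement. For an even gene count the median is the
#' arithmetic mean of the two central order statistics (R's default).
#'
#' @param table an `ExpressionTable` tibble.
#' @return the table with `value` rescaled so every measurement has median 1.
#' @export
normalize_sample_median <- function(table) {
  validate_expression_table(table)
  if (any(table$value <= 0)) {
    bad <- table[table$value <= 0, c("gene", "cell", "time_h", "sample", "replicate")]
    abort_data(paste0("non-positive values in records: ",
                      paste(utils::capture.output(print(bad, n = 5)), collapse = "\n")))
  }
  table %>%
    group_by(.data$cell, .data$time_h, .data$sample, .data$replicate) %>%
    mutate(value = .data$value / median(.data$value)) %>%
    ungroup()
}

#' Normalize each gene to its geometric mean over all values
#'
#' Applied after [normalize_sample_median()]: separately for each gene, every
#' value is divided by the geometric mean of all retained values of that
#' gene, computed in log space.
#'
#' @param table an `ExpressionTable` tibble with positive values.
#' @param floor optional detection floor: values below it raise a data error
#'   by default, or are clamped to it when `clamp = TRUE`.
#' @param clamp clamp sub-floor values instead of rejecting them.
#' @return the table with per-gene geometric mean 1.
#' @export
normalize_gene_geomean <- function(table, floor = 0, clamp = FALSE) {
  validate_expression_table(table)
  if (any(table$value < floor) && clamp) {
    table$value <- pmax(table$value, floor)
  }
  if (any(table$value <= max(0, floor) & !clamp) && any(table$value <= 0)) {
    abort_data("non-positive expression values; geometric mean undefined")
  }
  table %>%
    group_by(.data$gene) %>%
    mutate(value = .data$value / exp(mean(log(.data$value)))) %>%
    ungroup()
}

#' Replicate x-fold deviations and the two-fold QC flags
#'
#' For every replicate group — the 2 technical replicates of a sample
#' (`group = "pair"`) or all 4 measurements of the two samples of a cell at
#' one time point (`group = "quad"`) — each value's x-fold deviation
#' `r = value / mean(group)` is computed. For a pair, `r1 + r2 = 2` exactly.
#' A measurement fails the two-fold rule when `r` falls outside
#' `[1/fold_limit, fold_limit]`.
#'
#' @param table an `ExpressionTable`.
#' @param group `"pair"` (replicates within a sample) or `"quad"` (all four
#'   measurements of a cell at a time point).
#' @param fold_limit threshold of the flagging rule (default 2).
#' @return a `qc_report`: list with `deviations` (the table plus `r`,
#'   `log2_r`, `pass`), `group`, `fold_limit`, and `excluded_plasmodia`
#'   (empty here; filled by [apply_qc_filters()]).
#' @export
replicate_deviations <- function(table, group = c("pair", "quad"), fold_limit = 2) {
  group <- match.arg(group)
  validate_expression_table(table)
  keys <- switch(group,
                 pair = c("gene", "cell", "time_h", "sample"),
                 quad = c("gene", "cell", "time_h"))
  expected <- switch(group, pair = 2L, quad = 4L)
  dev <- table %>%
    group_by(across(all_of(keys))) %>%
    mutate(.n = dplyr::n(), r = .data$value / mean(.data$value)) %>%
    ungroup()
  if (any(dev$.n != expected)) {
    bad <- distinct(dev[dev$.n != expected, keys])
    abort_data(paste0("incomplete replicate group(s): ",
                      paste(apply(bad, 1, paste, collapse = "/"), collapse = "; ")))
  }
  dev <- dev %>%
    mutate(log2_r = log2(.data$r),
           pass = .data$r >= 1 / fold_limit & .data$r <= fold_limit) %>%
    select(-".n")
  structure(list(deviations = dev, group = group, fold_limit = fold_limit,
                 excluded_plasmodia = character(0)),
            class = "qc_report")
}

#' Quantile table of replicate deviations
#'
#' Summarizes a QC report's deviations as a quantile table with one row per
#' probability: the log2 quantile and the corresponding fold quantile
#' `2^log2`.
#'
#' @param report a [replicate_deviations()] report.
#' @param probs probabilities in (0, 1); the default mirrors the customary
#'   1/5/25/50/75/95/99 percent layout.
#' @return tibble with columns `prob`, `log2_q`, `fold_q`.
#' @export
deviation_quantiles <- function(report,
                                probs = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)) {
  stopifnot(inherits(report, "qc_report"))
  if (nrow(report$deviations) == 0) abort_data("no deviations to summarize")
  if (any(probs <= 0 | probs >= 1)) abort_arg("probs must lie strictly in (0, 1)")
  lq <- unname(quantile(report$deviations$log2_r, probs))
  tibble(prob = probs, log2_q = lq, fold_q = 2^lq)
}

#' Apply the two-fold replicate rule and the plasmodium-exclusion rule
#'
#' Two filters: (i) replicate groups containing a measurement whose x-fold
#' deviation from the group mean exceeds `fold_limit` are removed (the whole
#' group, since a discordant pair identifies no culprit); (ii) a plasmodium
#' is excluded wholesale when one of its samples disagrees with its sibling
#' sample(s) taken at the same time point by more than `fold_limit`,
#' measured as the median over genes of the ratio of the sample's replicate
#' means to the per-gene median across that cell-time point's samples.
#'
#' @param table an `ExpressionTable`.
#' @param report QC report from [replicate_deviations()] on the same table.
#' @param fold_limit exclusion threshold (> 1; default 2).
#' @return the filtered table, with attributes `n_removed_measurements` and
#'   `excluded_plasmodia`.
#' @export
apply_qc_filters <- function(table, report, fold_limit = 2) {
  stopifnot(inherits(report, "qc_report"))
  if (fold_limit <= 1) abort_arg("fold_limit must exceed 1")
  dev <- report$deviations
  keys <- switch(report$group,
                 pair = c("gene", "cell", "time_h", "sample"),
                 quad = c("gene", "cell", "time_h"))
  bad_groups <- dev %>%
    group_by(across(all_of(keys))) %>%
    summarise(ok = all(.data$r >= 1 / fold_limit & .data$r <= fold_limit),
              .groups = "drop") %>%
    filter(!.data$ok) %>% select(-"ok")
  kept <- dplyr::anti_join(table, bad_groups, by = keys)
  n_removed <- nrow(table) - nrow(kept)

  # plasmodium-level exclusion: compare sibling samples at each time point
  sample_prof <- kept %>%
    group_by(.data$cell, .data$time_h, .data$sample, .data$gene) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ref <- sample_prof %>%
    group_by(.data$cell, .data$time_h, .data$gene) %>%
    summarise(ref = median(.data$value), n_samples = n_distinct(.data$sample),
              .groups = "drop")
  ratios <- sample_prof %>%
    left_join(ref, by = c("cell", "time_h", "gene")) %>%
    filter(.data$n_samples > 1) %>%
    group_by(.data$cell, .data$time_h, .data$sample) %>%
    summarise(med_ratio = median(.data$value / .data$ref), .groups = "drop")
  excluded <- unique(ratios$cell[ratios$med_ratio > fold_limit |
                                   ratios$med_ratio < 1 / fold_limit])
  out <- kept[!kept$cell %in% excluded, ]
  attr(out, "n_removed_measurements") <- n_removed
  attr(out, "excluded_plasmodia") <- excluded
  out
}

#' Aggregate replicates to one expression value per gene, cell and time point
#'
#' Takes the arithmetic mean of all surviving replicate values (up to four:
#' two samples x two technical replicates) for each gene at each cell and
#' time point.
#'
#' @param table a normalized, filtered `ExpressionTable`.
#' @return tibble with columns `gene`, `cell`, `time_h`, `value`, `n_values`.
#' @export
aggregate_measurements <- function(table) {
  validate_expression_table(table)
  table %>%
    group_by(.data$gene, .data$cell, .data$time_h) %>%
    summarise(value = mean(.data$value), n_values = n(), .groups = "drop")
}

#' Aggregate with a fallback for combinations erased by the replicate rule
#'
#' A discordant replicate pair identifies no culprit, so [apply_qc_filters()]
#' removes the whole pair — which can leave a gene with no surviving value at
#' one cell-time point. This wrapper aggregates the filtered table and fills
#' exactly those holes with the mean over all (unfiltered) replicates, so the
#' expression matrix and every trajectory stay complete; the number of
#' refilled combinations is recorded in `attr(, "n_refilled")`.
#'
#' @param filtered output of [apply_qc_filters()].
#' @param full the same table before the replicate filter (excluded
#'   plasmodia are dropped from it automatically).
#' @return tibble as from [aggregate_measurements()].
#' @export
aggregate_with_fallback <- function(filtered, full) {
  agg <- aggregate_measurements(filtered)
  excl <- attr(filtered, "excluded_plasmodia")
  agg_all <- aggregate_measurements(full[!full$cell %in% excl, ])
  holes <- dplyr::anti_join(agg_all, agg, by = c("gene", "cell", "time_h"))
  out <- arrange(bind_rows(agg, holes), .data$gene, .data$cell, .data$time_h)
  attr(out, "n_refilled") <- nrow(holes)
  out
}

#' Pivot an aggregated table to a cell-time point x gene matrix
#'
#' @param aggregated output of [aggregate_measurements()].
#' @return numeric matrix; rows named `cell@time_h`, columns are genes.
#'   Missing combinations raise a data error naming the holes.
#' @export
expression_matrix <- function(aggregated) {
  wide <- tidyr::pivot_wider(aggregated[, c("gene", "cell", "time_h", "value")],
                             names_from = "gene", values_from = "value")
  m <- as.matrix(wide[, setdiff(names(wide), c("cell", "time_h"))])
  rownames(m) <- sprintf("%s@%g", wide$cell, wide$time_h)
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    abort_data(paste0("missing expression values at: ",
                      paste(sprintf("%s x %s", rownames(m)[holes[, 1]],
                                    colnames(m)[holes[, 2]]), collapse = ", ")))
  }
  m
}
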