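#' Count read pairs per fully sequenced index
#'
#' Tallies read-pair multiplicity for every index that contains no ambiguous
#' base; pairs whose index carries an `N` are excluded and counted separately.
#' This is the table behind multiplicity binning: indices with many associated
#' pairs are strongly enriched for the high-copy organelle.
#'
#' @param reads Read-pair tibble with an `index` column.
#' @return An `index_count_table`: tibble (`index`, `n_pairs`) sorted by
#'   decreasing count, with attributes `total_pairs` and `excluded_ambiguous`.
#' @export
#' @examples
#' reads <- tibble::tibble(pair_id = c("a", "b", "c"),
#'                         index = c("AAAA", "AAAA", "CCNN"))
#' count_index_multiplicity(reads)
count_index_multiplicity <- function(reads) {
  if (!"index" %in% names(reads)) stopf("reads must have an 'index' column")
  bad <- which(is.na(reads$index) | reads$index == "")
  if (length(bad)) {
    id <- if ("pair_id" %in% names(reads)) reads$pair_id[bad[1]] else bad[1]
    stopf("read pair '%s' lacks a barcode index", id)
  }
  ambiguous <- grepl("N", reads$index, fixed = TRUE)
  tab <- table(reads$index[!ambiguous])
  out <- tibble(index = as.character(if (length(tab)) names(tab) else character(0)),
                n_pairs = as.integer(tab)) %>%
    arrange(desc(.data$n_pairs), .data$index)
  attr(out, "total_pairs") <- nrow(reads)
  attr(out, "excluded_ambiguous") <- sum(ambiguous)
  class(out) <- c("index_count_table", class(out))
  out
}

#' @export
print.index_count_table <- function(x, ...) {
  cat(sprintf("<index_count_table> %d indices, %d pairs (%d excluded for ambiguous index)\n",
              nrow(x), attr(x, "total_pairs"), attr(x, "excluded_ambiguous")))
  NextMethod()
}

#' Extract a multiplicity-threshold read bin
#'
#' Keeps every read pair whose index has at least `threshold` associated
#' pairs ("at least": inclusive), preserving input order.
#'
#' @param reads Read-pair tibble the `table` was built from.
#' @param table An [count_index_multiplicity()] table.
#' @param threshold Minimum pairs per index (>= 1).
#' @return A `read_bin`: the filtered read tibble with attributes `threshold`,
#'   `indices` (the qualifying index set) and `fraction_of_total`.
#' @export
bin_reads <- function(reads, table, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1) {
    stopf("invalid configuration: field 'threshold' must be >= 1")
  }
  keep_idx <- table$index[table$n_pairs >= threshold]
  out <- reads[reads$index %in% keep_idx, , drop = FALSE]
  total <- attr(table, "total_pairs")
  attr(out, "threshold") <- threshold
  attr(out, "indices") <- keep_idx
  attr(out, "fraction_of_total") <- if (isTRUE(total > 0)) nrow(out) / total else 0
  class(out) <- c("read_bin", setdiff(class(out), "index_count_table"))
  out
}

#' @export
print.read_bin <- function(x, ...) {
  cat(sprintf("<read_bin> threshold >= %s: %d pairs from %d indices (%.1f%% of all pairs)\n",
              format(attr(x, "threshold")), nrow(x), length(attr(x, "indices")),
              100 * attr(x, "fraction_of_total")))
  NextMethod()
}

#' Index multiplicity histogram and threshold summary
#'
#' Returns per-index counts in ascending order plus, for each requested
#' threshold, the number of qualifying indices, their total pair count and
#' the fraction of all pairs they capture.
#'
#' @param table An [count_index_multiplicity()] table.
#' @param thresholds Numeric thresholds for the summary rows.
#' @return List with `counts` (ascending integer vector) and `summary`
#'   (tibble: `threshold`, `n_indices`, `n_pairs`, `fraction`).
#' @export
multiplicity_histogram <- function(table, thresholds = numeric(0)) {
  counts <- sort(table$n_pairs)
  total <- attr(table, "total_pairs")
  if (is.null(total)) total <- sum(table$n_pairs)
  summary <- tibble(
    threshold = as.numeric(thresholds),
    n_indices = vapply(thresholds, function(t) sum(table$n_pairs >= t), 0L),
    n_pairs = vapply(thresholds, function(t) sum(table$n_pairs[table$n_pairs >= t]), 0L),
    fraction = vapply(thresholds, function(t) {
      if (isTRUE(total > 0)) sum(table$n_pairs[table$n_pairs >= t]) / total else 0
    }, 0)
  )
  list(counts = counts, summary = summary)
}

#' Threshold capturing a top fraction of read pairs
#'
#' The largest multiplicity threshold whose bin still captures at least
#' `fraction` of all read pairs; used to pick bin cut-offs analogous to
#' fixed-count bins on libraries of any depth.
#'
#' @param table An [count_index_multiplicity()] table.
#' @param fraction Target fraction of all pairs, in (0, 1].
#' @return Integer threshold (>= 1).
#' @export
threshold_for_top_fraction <- function(table, fraction) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  total <- attr(table, "total_pairs")
  if (is.null(total) || total == 0) return(1L)
  cand <- sort(unique(table$n_pairs), decreasing = TRUE)
  for (t in cand) {
    if (sum(table$n_pairs[table$n_pairs >= t]) / total >= fraction) return(as.integer(t))
  }
  1L
}

#' Plot the index multiplicity distribution
#'
#' Indices in ascending order of associated read-pair count, with optional
#' horizontal lines at bin thresholds.
#'
#' @param table An [count_index_multiplicity()] table.
#' @param thresholds Optional thresholds to mark.
#' @return A ggplot object.
#' @export
plot_multiplicity <- function(table, thresholds = numeric(0)) {
  df <- tibble(rank = seq_len(nrow(table)), n_pairs = sort(table$n_pairs))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$n_pairs)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "index (ascending multiplicity)",
                  y = "read pairs per index") +
    ggplot2::theme_minimal()
  if (length(thresholds)) {
    p <- p + ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}
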