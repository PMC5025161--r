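#' Tidy a gap-fill report
#'
#' @param x A `gap_fill_report` from [fill_all_gaps()].
#' @param ... Unused.
#' @return The per-round, per-gap attempt tibble.
#' @export
tidy.gap_fill_report <- function(x, ...) {
  x$results
}

#' Tidy a coverage report
#'
#' @param x A `coverage_report` from [read_coverage()].
#' @param ... Unused.
#' @return Tibble (`position`, `depth`); positions are 1-based.
#' @export
tidy.coverage_report <- function(x, ...) {
  tibble(position = seq_along(x$depth), depth = x$depth)
}

#' One-row summary of a coverage report
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @return Tibble (`fraction_covered`, `mean_depth`, `n_positions`,
#'   `n_reads`).
#' @export
glance.coverage_report <- function(x, ...) {
  tibble(fraction_covered = x$fraction, mean_depth = mean(x$depth),
         n_positions = length(x$depth), n_reads = x$n_reads)
}

#' Tidy a run report's stage log
#'
#' @param x A `run_report` from [run_all()].
#' @param ... Unused.
#' @return The per-stage log tibble.
#' @export
tidy.run_report <- function(x, ...) {
  x$stages
}

#' One-row summary of a pipeline run
#'
#' @param x A `run_report` from [run_all()].
#' @param ... Unused.
#' @return Tibble with headline numbers: contig/scaffold counts, gap-fill
#'   outcome, final genome size and (for simulated runs) truth agreement.
#' @export
glance.run_report <- function(x, ...) {
  tibble(
    n_pairs = attr(x$index_counts, "total_pairs"),
    n_contigs = nrow(x$contigs),
    n_scaffolds = nrow(x$scaffolds),
    gaps_closed = sum(x$fill_results$status == "closed"),
    gaps_remaining = x$gaps_remaining,
    circular = x$circular,
    final_length = nchar(x$genome),
    gc = x$composition$gc,
    ir_length = if (!is.null(x$ir) && nrow(x$ir)) x$ir$length else NA_integer_,
    ir_substitutions = if (!is.null(x$ir) && nrow(x$ir)) x$ir$substitutions else NA_integer_,
    exact_match = if (!is.null(x$truth_comparison)) x$truth_comparison$exact else NA
  )
}
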