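#' Nucleotide composition of a genome
#'
#' Percentages of A/C/G/T over unambiguous bases only (ambiguous IUPAC codes
#' are excluded from the denominator), plus GC percent and total length.
#'
#' @param genome Character scalar sequence.
#' @return A `composition_report` tibble (one row: `a`, `c`, `g`, `t`, `gc`,
#'   `length`, `denominator`).
#' @export
#' @examples
#' composition("ACGT")
composition <- function(genome) {
  if (!nchar(genome)) stopf("cannot compute composition of an empty sequence")
  x <- Biostrings::DNAString(toupper(genome))
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) stopf("sequence has no unambiguous bases")
  pct <- 100 * as.numeric(f) / denom
  out <- tibble(a = pct[1], c = pct[2], g = pct[3], t = pct[4],
                gc = pct[2] + pct[3], length = nchar(genome),
                denominator = denom)
  class(out) <- c("composition_report", class(out))
  out
}

#' Ambiguity and gap accounting
#'
#' Counts every IUPAC-ambiguous base (anything outside A/C/G/T) as ambiguous
#' and summarises maximal `N` runs: count, mean length and sample (n-1)
#' standard deviation (population sd is also reported).
#'
#' @param genome Character scalar sequence.
#' @return An `ambiguity_report` tibble (one row: `length`, `resolved`,
#'   `ambiguous`, `n_runs`, `run_mean`, `run_sd`, `run_sd_pop`).
#' @export
#' @examples
#' ambiguity_stats("ACNNNGT")
ambiguity_stats <- function(genome) {
  g <- toupper(genome)
  L <- nchar(g)
  resolved <- if (L) {
    sum(as.numeric(Biostrings::letterFrequency(Biostrings::DNAString(g),
                                               c("A", "C", "G", "T"))))
  } else 0
  runs <- find_gaps(g)
  run_len <- runs$end - runs$start
  out <- tibble(
    length = L,
    resolved = resolved,
    ambiguous = L - resolved,
    n_runs = nrow(runs),
    run_mean = if (nrow(runs)) mean(run_len) else 0,
    run_sd = if (nrow(runs) > 1) sd(run_len) else 0,
    run_sd_pop = if (nrow(runs)) sqrt(mean((run_len - mean(run_len))^2)) else 0
  )
  class(out) <- c("ambiguity_report", class(out))
  out
}

#' Reference coverage by exact-seed ungapped read placement
#'
#' Each read is placed at the locus of its first unique exact `seed_k`-mer
#' match (scanning from the 5' end, reverse-complement aware) and extended
#' without gaps; unplaced reads are ignored. This deliberately simple
#' placement is adequate for presence/absence coverage at <= 1% divergence.
#'
#' @param reference Reference sequence.
#' @param reads Read-pair tibble or character vector of reads.
#' @param seed_k Seed length (default 19).
#' @return A `coverage_report`: list with `depth` (integer vector over
#'   reference positions), `fraction` (share of positions with depth >= 1)
#'   and `n_reads`.
#' @export
read_coverage <- function(reference, reads, seed_k = 19) {
  seqs <- as_sequences(reads)
  depth <- cpp_read_coverage(toupper(reference), toupper(seqs),
                             as.integer(seed_k))
  structure(list(depth = depth, fraction = mean(depth >= 1),
                 n_reads = length(seqs)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %.2f%% of %d positions covered (%d reads placed over them)\n",
              100 * x$fraction, length(x$depth), x$n_reads))
  invisible(x)
}

#' @rdname read_coverage
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- tibble(position = seq_along(object$depth), depth = object$depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::labs(x = "reference position (bp)", y = "read depth") +
    ggplot2::theme_minimal()
}

#' Detect a two-copy inverted repeat
#'
#' Collects all maximal exact matches of at least `min_anchor` bp between the
#' genome and its reverse complement, merges anchors lying on the same
#' anti-diagonal (substitution-separated pieces of one repeat), counts
#' inter-anchor bases as substitutions, and reports the longest merged pair
#' with disjoint copies — the hallmark short IR of conifer plastomes.
#'
#' @param genome Character scalar sequence.
#' @param min_anchor Minimum exact anchor length (default 24).
#' @return An `ir_report` tibble (one row: `start1`, `end1`, `start2`,
#'   `end2`, `length`, `substitutions`; 0-based half-open coordinates), or a
#'   zero-row tibble when no anchor is found.
#' @export
detect_inverted_repeat <- function(genome, min_anchor = 24) {
  g <- toupper(genome)
  if (nchar(g) < 2 * min_anchor) {
    stopf("sequence shorter than two anchors (%d bp)", 2 * min_anchor)
  }
  empty <- tibble(start1 = integer(0), end1 = integer(0), start2 = integer(0),
                  end2 = integer(0), length = integer(0),
                  substitutions = integer(0))
  class(empty) <- c("ir_report", class(empty))
  m <- as_tibble(cpp_ir_matches(g, as.integer(min_anchor)))
  if (nrow(m) == 0) return(empty)
  # anti-diagonal: start1 + start2 + len is constant across anchors of one
  # substitution-separated inverted pair
  m <- m %>%
    mutate(diag = .data$start1 + .data$start2 + .data$len) %>%
    arrange(.data$diag, .data$start1)
  best <- NULL
  for (dg in unique(m$diag)) {
    part <- m[m$diag == dg, , drop = FALSE]
    # merge consecutive anchors; the gap between anchor i and i+1 along copy 1
    # equals the substitution run separating them
    s1 <- min(part$start1)
    e1 <- max(part$start1 + part$len)
    subs <- (e1 - s1) - sum(part$len)
    s2 <- min(part$start2)
    e2 <- max(part$start2 + part$len)
    if (e1 <= s2 || e2 <= s1) { # disjoint copies only
      cand <- tibble(start1 = s1, end1 = e1, start2 = s2, end2 = e2,
                     length = e1 - s1, substitutions = subs)
      if (is.null(best) || cand$length > best$length) best <- cand
    }
  }
  if (is.null(best)) return(empty)
  class(best) <- c("ir_report", class(best))
  best
}

#' Rotation-aware comparison of an assembly to its truth
#'
#' For circular genomes the assembly is canonically rotated (both strands
#' tried, anchored on the truth) before comparison. Reports an exact-match
#' flag, the length difference, and the mismatch count when lengths agree.
#'
#' @param assembly Assembled sequence.
#' @param truth True sequence.
#' @param circular Rotate/complement the assembly before comparing (default
#'   `TRUE`).
#' @return Tibble (one row: `exact`, `length_diff`, `n_mismatch`;
#'   `n_mismatch` is `NA` when lengths differ).
#' @export
compare_to_truth <- function(assembly, truth, circular = TRUE) {
  a <- toupper(assembly)
  t <- toupper(truth)
  if (circular) {
    a <- canonical_rotation(a, reference = t)
    t_rot <- t
  } else {
    t_rot <- t
  }
  ld <- nchar(a) - nchar(t_rot)
  nm <- NA_integer_
  if (ld == 0) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    tv <- strsplit(t_rot, "", fixed = TRUE)[[1]]
    nm <- sum(av != tv)
  }
  tibble(exact = identical(a, t_rot), length_diff = ld, n_mismatch = nm)
}
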