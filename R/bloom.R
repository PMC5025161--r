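#' Build a Bloom filter over canonical k-mers
#'
#' Inserts every canonical k-mer of the input sequences into a bit array
#' sized from the number of insertions `n` and the target false-positive rate
#' `f`: `m = ceil(-n ln f / (ln 2)^2)` bits and `h = round((m/n) ln 2)` hash
#' functions (double hashing over two independent 64-bit streams). Bloom
#' membership has no false negatives; false positives occur at roughly the
#' target rate.
#'
#' @param seqs Character vector of sequences or a read-pair tibble.
#' @param k K-mer length (default 25).
#' @param target_fpr Target false-positive rate (default 0.001).
#' @return A `bloom_filter` object (fields `bits`, `k`, `m`, `h`, `n`,
#'   `target_fpr`).
#' @export
build_bloom <- function(seqs, k = 25, target_fpr = 0.001) {
  seqs <- as_sequences(seqs)
  short <- nchar(seqs) < k
  if (any(short)) {
    warn(sprintf("%d sequence(s) shorter than k = %d skipped", sum(short), k))
    seqs <- seqs[!short]
  }
  bf <- cpp_bloom_build(toupper(seqs), as.integer(k), target_fpr)
  structure(bf, class = "bloom_filter")
}

#' @export
print.bloom_filter <- function(x, ...) {
  cat(sprintf("<bloom_filter> k = %d, m = %s bits, h = %d, n = %s inserted (target FPR %g)\n",
              x$k, format(x$m, big.mark = ","), x$h,
              format(x$n, big.mark = ","), x$target_fpr))
  invisible(x)
}

#' Bloom filter membership
#'
#' @param bf A [build_bloom()] filter.
#' @param kmers Character vector of k-mers (either strand).
#' @return Logical vector (no false negatives).
#' @export
bloom_contains <- function(bf, kmers) {
  cpp_bloom_contains(bf$bits, bf$m, bf$h, bf$k, toupper(kmers))
}

#' Classify read pairs against a Bloom filter
#'
#' A pair is kept when the larger of its two per-mate k-mer hit shares (the
#' fraction of a read's k-mers present in the filter) reaches `min_share`.
#' Pairs are kept intact — either mate passing keeps both — so pairs spanning
#' the boundary of the filtered locus survive for downstream gap filling.
#'
#' @param reads Read-pair tibble.
#' @param bf A [build_bloom()] filter.
#' @param min_share Minimum k-mer hit share in `[0, 1]` (default 0.15, which
#'   tolerates ~1% reference divergence plus sequencing error at k = 25).
#' @return The kept subset of `reads`, with per-pair share in attribute
#'   `share`.
#' @export
classify_reads <- function(reads, bf, min_share = 0.15) {
  s1 <- cpp_bloom_share(bf$bits, bf$m, bf$h, bf$k, reads$read1)
  s2 <- cpp_bloom_share(bf$bits, bf$m, bf$h, bf$k, reads$read2)
  share <- pmax(s1, s2)
  keep <- share >= min_share
  out <- reads[keep, , drop = FALSE]
  attr(out, "share") <- share[keep]
  out
}
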