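#' Reverse complement
#'
#' Vectorised reverse complement over plain character sequences. Bases outside
#' A/C/G/T become `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AACCN"))
revcomp <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

#' Canonical k-mer form
#'
#' The lexicographic minimum of a k-mer and its reverse complement.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  cpp_canonical(toupper(as.character(x)))
}

# i.i.d. uniform A/C/G/T sequence of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Fixed fan-out of one user seed into per-stage seeds (Lehmer step), kept
# below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + 11 * stage) %% 2147483629
}

stopf <- function(...) abort(sprintf(...))

check_scalar_number <- function(value, field, min = -Inf, max = Inf) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < min || value > max) {
    stopf("invalid configuration: field '%s' must be a number in [%s, %s]",
          field, format(min), format(max))
  }
  invisible(value)
}

# substring of a circular sequence, 0-based start, may wrap (also multiple times)
substr_circular <- function(seq, start, len) {
  L <- nchar(seq)
  start <- start %% L
  if (start + len <= L) {
    substr(seq, start + 1, start + len)
  } else {
    tiled <- strrep(seq, ceiling((start + len) / L))
    substr(tiled, start + 1, start + len)
  }
}
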