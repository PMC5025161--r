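#' Quality-trim read pairs
#'
#' 3' trimming by the running-sum argmax rule: each read is cut at the
#' position maximising the sum of `(q - Q_i)` over the removed suffix (the
#' classic modified-Mott rule). Pairs in which either trimmed mate falls below
#' `min_len` are dropped and counted.
#'
#' @param reads Read-pair tibble (`read1`, `qual1`, `read2`, `qual2`,
#'   Phred+33).
#' @param q Quality threshold (default 15).
#' @param min_len Minimum kept read length; shorter reads drop the pair.
#' @return The trimmed tibble with attribute `dropped_pairs`.
#' @export
trim_reads <- function(reads, q = 15, min_len = 48) {
  if (any(nchar(reads$qual1) != nchar(reads$read1)) ||
      any(nchar(reads$qual2) != nchar(reads$read2))) {
    bad <- which(nchar(reads$qual1) != nchar(reads$read1) |
                   nchar(reads$qual2) != nchar(reads$read2))[1]
    id <- if ("pair_id" %in% names(reads)) reads$pair_id[bad] else bad
    stopf("malformed quality string for record '%s'", id)
  }
  keep1 <- cpp_trim_point(reads$qual1, q)
  keep2 <- cpp_trim_point(reads$qual2, q)
  out <- reads
  out$read1 <- substr(out$read1, 1L, keep1)
  out$qual1 <- substr(out$qual1, 1L, keep1)
  out$read2 <- substr(out$read2, 1L, keep2)
  out$qual2 <- substr(out$qual2, 1L, keep2)
  ok <- keep1 >= min_len & keep2 >= min_len
  res <- out[ok, , drop = FALSE]
  attr(res, "dropped_pairs") <- sum(!ok)
  res
}

# read tibble or plain character vector -> sequence vector
as_sequences <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    cols <- intersect(c("read1", "read2", "sequence"), names(x))
    if (length(cols)) return(unlist(x[cols], use.names = FALSE))
  }
  stopf("cannot interpret input as sequences (want a character vector or a read tibble)")
}

#' Build a canonical k-mer de Bruijn graph
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) over the input sequences; entries below `min_count` are
#' removed. The graph is implicit: vertices are canonical k-mers and edges are
#' (k-1)-base overlaps looked up on demand, reverse-complement aware.
#'
#' @param x Read-pair tibble (both mates are used) or character vector of
#'   sequences.
#' @param k K-mer length (default 48; odd k avoids palindromic k-mers and is
#'   recommended — an even k is accepted with a warning).
#' @param min_count Minimum multiplicity kept (default 2, which removes most
#'   singleton sequencing-error k-mers).
#' @return A `kmer_graph` object.
#' @export
build_kmer_graph <- function(x, k = 48, min_count = 2) {
  seqs <- as_sequences(x)
  if (length(seqs) && k > max(nchar(seqs))) {
    stopf("invalid configuration: field 'k' (%d) exceeds the longest sequence (%d bp)",
          k, max(nchar(seqs)))
  }
  if (k %% 2 == 0) {
    warn(sprintf("even k (%d): canonical ties on palindromic k-mers are broken lexicographically", k),
         class = "plastidlinker_even_k")
  }
  ptr <- cpp_kgraph_build(toupper(seqs), as.integer(k), as.integer(min_count))
  structure(list(ptr = ptr, k = as.integer(k), min_count = as.integer(min_count),
                 n_vertices = cpp_kgraph_size(ptr)),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("<kmer_graph> k = %d, %s vertices (min_count = %d)\n",
              x$k, format(x$n_vertices, big.mark = ","), x$min_count))
  invisible(x)
}

#' Materialise a k-mer graph as a tibble
#'
#' Intended for inspection and testing on small graphs; a deep-coverage graph
#' can hold millions of vertices.
#'
#' @param g A [build_kmer_graph()] object.
#' @return Tibble (`kmer`, `count`), lexicographically sorted.
#' @export
kmer_graph_table <- function(g) {
  as_tibble(cpp_kgraph_table(g$ptr))
}

#' K-mer membership in a graph
#'
#' @param g A [build_kmer_graph()] object.
#' @param kmers Character vector of k-mers (either strand).
#' @return Logical vector.
#' @export
graph_contains <- function(g, kmers) {
  cpp_kgraph_contains(g$ptr, toupper(kmers))
}

#' Assemble unitigs from a k-mer graph
#'
#' Emits maximal non-branching paths: every internal vertex has exactly one
#' predecessor and one successor under reverse-complement-aware adjacency. No
#' tip or bubble removal is performed — in this workflow the multiplicity
#' binning, not graph simplification, is what keeps the graph clean.
#' Branch-free circular components yield one contig opened at their
#' lexicographically minimal canonical k-mer. Output is deterministic
#' (contigs in canonical orientation, sorted).
#'
#' @param g A [build_kmer_graph()] object.
#' @param min_len Minimum contig length in bp (default 500).
#' @return Tibble (`id`, `sequence`, `length`, `coverage`) where `coverage`
#'   is the mean multiplicity of the contig's k-mers.
#' @export
build_unitigs <- function(g, min_len = 500) {
  if (g$n_vertices == 0) stopf("cannot assemble an empty graph")
  res <- cpp_kgraph_unitigs(g$ptr, as.integer(min_len))
  n <- length(res$sequence)
  tibble(
    id = if (n) sprintf("contig%04d", seq_len(n)) else character(0),
    sequence = res$sequence,
    length = nchar(res$sequence),
    coverage = res$coverage
  )
}

#' Blunt-end fraction of a k-mer graph
#'
#' Fraction of k-mer vertices with no neighbour in at least one extension
#' direction — a simple measure of de Bruijn graph complexity/fragmentation:
#' clean deep-coverage graphs of a closed genome approach 0, read sets mixing
#' thin background coverage score much higher.
#'
#' @param g A [build_kmer_graph()] object.
#' @return Proportion in `[0, 1]`.
#' @export
blunt_end_fraction <- function(g) {
  if (g$n_vertices == 0) stopf("blunt-end fraction is undefined on an empty graph")
  cpp_kgraph_blunt_fraction(g$ptr)
}
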