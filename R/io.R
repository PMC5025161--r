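#' Write linked reads as paired FASTQ
#'
#' Writes `<prefix>_1.fastq` and `<prefix>_2.fastq` (add `.gz` via
#' `compress = TRUE`). The partition index travels in the header comment as
#' `BX:Z:<14-mer>` on both mates.
#'
#' @param reads Read-pair tibble as produced by [simulate_linked_reads()].
#' @param prefix Output path prefix.
#' @param compress Write gzip-compressed files.
#' @return Invisibly, the two file paths.
#' @export
write_linked_fastq <- function(reads, prefix, compress = FALSE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  hdr <- paste0(reads$pair_id, " BX:Z:", reads$index)
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("read", mate)]])
    names(seqs) <- hdr
    quals <- Biostrings::BStringSet(reads[[paste0("qual", mate)]])
    Biostrings::writeXStringSet(seqs, paths[mate], format = "fastq",
                                qualities = quals,
                                compress = if (compress) "gzip" else FALSE)
  }
  invisible(paths)
}

#' Read paired FASTQ with linked-read barcodes
#'
#' Two barcode dialects are supported: `"comment"` parses `BX:Z:<index>` from
#' the header comment of read 1; `"inline"` takes the first 14 bases of read 1
#' as the index and trims them (with their qualities) from the read.
#'
#' @param path1,path2 FASTQ paths for mates 1 and 2.
#' @param barcode Either `"comment"` (default) or `"inline"`.
#' @param barcode_length Index length for the inline dialect.
#' @return Read-pair tibble (`pair_id`, `index`, `read1`, `qual1`, `read2`,
#'   `qual2`).
#' @export
read_linked_fastq <- function(path1, path2, barcode = c("comment", "inline"),
                              barcode_length = 14L) {
  barcode <- match.arg(barcode)
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stopf("mate files differ in record count")
  ids <- sub("[[:space:]].*$", "", names(r1))
  seq1 <- as.character(r1)
  seq2 <- as.character(r2)
  q1 <- as.character(S4Vectors::mcols(r1)$qualities)
  q2 <- as.character(S4Vectors::mcols(r2)$qualities)
  if (barcode == "comment") {
    m <- regmatches(names(r1), regexpr("BX:Z:[ACGTN]+", names(r1)))
    idx <- rep(NA_character_, length(r1))
    has <- grepl("BX:Z:", names(r1), fixed = TRUE)
    idx[has] <- sub("^BX:Z:", "", m)
  } else {
    idx <- substr(seq1, 1, barcode_length)
    seq1 <- substr(seq1, barcode_length + 1L, nchar(seq1))
    q1 <- substr(q1, barcode_length + 1L, nchar(q1))
  }
  tibble(pair_id = unname(ids), index = unname(idx),
         read1 = unname(seq1), qual1 = unname(q1),
         read2 = unname(seq2), qual2 = unname(q2))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (unnamed sequences are
#'   given `seq1`, `seq2`, ... identifiers).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write the per-pair ground truth table as TSV
#'
#' @param truth Truth tibble from [simulate_linked_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' Serialise a Bloom filter
#'
#' Text serialisation: a one-line JSON header carrying `k`, `m`, `h`, `n` and
#' the target false-positive rate, followed by the base64-encoded bit array.
#'
#' @param bf A [build_bloom()] filter.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bloom <- function(bf, path) {
  hdr <- jsonlite::toJSON(list(k = bf$k, m = bf$m, h = bf$h, n = bf$n,
                               target_fpr = bf$target_fpr), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(jsonlite::base64_enc(bf$bits), con)
  invisible(path)
}

#' Deserialise a Bloom filter written by [write_bloom()]
#'
#' @param path Input path.
#' @return A `bloom_filter` object.
#' @export
read_bloom <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  bits <- jsonlite::base64_dec(paste(lines[-1], collapse = ""))
  structure(list(bits = bits, k = hdr$k, m = hdr$m, h = hdr$h, n = hdr$n,
                 target_fpr = hdr$target_fpr),
            class = "bloom_filter")
}
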