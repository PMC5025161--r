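#' Locate scaffold gaps
#'
#' Maximal runs of `N`, left to right.
#'
#' @param scaffold Character scalar sequence over A/C/G/T/N.
#' @return Tibble (`start`, `end`), 0-based half-open.
#' @export
#' @examples
#' find_gaps("ACGNNNACG")
find_gaps <- function(scaffold) {
  m <- gregexpr("N+", scaffold, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(start = integer(0), end = integer(0)))
  tibble(start = as.integer(m) - 1L,
         end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Path-search limits
#'
#' @param B Maximum branch events before aborting (default 3000).
#' @param P Maximum distinct start-to-goal paths collected (default 20).
#' @param F Maximum flank search length in bp (default 5000); also bounds the
#'   outward slide when picking start/goal k-mers.
#' @return A `path_limits` list.
#' @export
path_limits <- function(B = 3000, P = 20, F = 5000) {
  for (nm in c("B", "P", "F")) {
    check_scalar_number(get(nm), nm, min = 1)
  }
  structure(list(B = B, P = P, F = F), class = "path_limits")
}

#' Default descending k sweep for gap filling
#'
#' 125 down to 95 in steps of 5, then 94 down to 35 in steps of 1.
#'
#' @return Strictly decreasing integer vector.
#' @export
default_k_sweep <- function() {
  c(seq(125L, 95L, by = -5L), seq(94L, 35L, by = -1L))
}

# membership oracle handle for cpp_path_search: bloom filter list or kmer_graph ptr
as_oracle <- function(x) {
  if (inherits(x, "bloom_filter")) return(x)
  if (inherits(x, "kmer_graph")) return(x$ptr)
  stopf("oracle must be a bloom_filter or kmer_graph")
}

oracle_has <- function(x, kmer) {
  if (inherits(x, "bloom_filter")) bloom_contains(x, kmer)
  else graph_contains(x, kmer)
}

# multiple-path resolution: a single path wins outright; several equal-length
# paths at >= 95% pairwise identity are resolved by column majority (ties take
# the first-found path's base); anything else is ambiguous.
consensus_paths <- function(paths, min_identity = 0.95) {
  if (length(paths) == 1L) return(list(status = "ok", fill = paths[1]))
  if (length(unique(nchar(paths))) != 1L) return(list(status = "ambiguous"))
  mat <- do.call(rbind, strsplit(paths, "", fixed = TRUE))
  np <- nrow(mat)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      if (mean(mat[i, ] == mat[j, ]) < min_identity) {
        return(list(status = "ambiguous"))
      }
    }
  }
  cons <- vapply(seq_len(ncol(mat)), function(c) {
    col <- mat[, c]
    tab <- table(col)
    best <- max(tab)
    winners <- names(tab)[tab == best]
    if (length(winners) == 1L) winners else col[1]
  }, "")
  list(status = "ok", fill = paste(cons, collapse = ""))
}

# One fill attempt at a fixed k over a membership oracle. Start k-mer is the
# k-mer immediately left of the gap, sliding outward (leftward) up to
# min(F, flank) bases when absent from the oracle; goal likewise on the right.
# Returns status plus, on success, the replaced scaffold interval (0-based,
# half-open; it may extend beyond the N run by the slide offsets) and the
# replacement sequence.
attempt_gap <- function(scaffold, gap_start, gap_end, oracle, k, limits) {
  L <- nchar(scaffold)
  # contiguous non-N flank lengths
  left_flank <- gap_start
  if (gap_start > 0) {
    prefix <- substr(scaffold, 1, gap_start)
    pn <- regexpr("[ACGT]+$", prefix, perl = TRUE)
    left_flank <- if (pn[1] == -1) 0L else attr(pn, "match.length")
  }
  suffix <- substr(scaffold, gap_end + 1, L)
  sn <- regexpr("^[ACGT]+", suffix, perl = TRUE)
  right_flank <- if (sn[1] == -1) 0L else attr(sn, "match.length")
  if (left_flank < k) return(list(status = "no_start_kmer"))
  if (right_flank < k) return(list(status = "no_goal_kmer"))

  find_anchor <- function(side) {
    max_slide <- min(limits$F, if (side == "left") left_flank - k else right_flank - k)
    for (off in 0:max_slide) {
      kmer <- if (side == "left") {
        substr(scaffold, gap_start - off - k + 1, gap_start - off)
      } else {
        substr(scaffold, gap_end + off + 1, gap_end + off + k)
      }
      if (oracle_has(oracle, kmer)) return(list(kmer = kmer, off = off))
    }
    NULL
  }
  start <- find_anchor("left")
  if (is.null(start)) return(list(status = "no_start_kmer"))
  goal <- find_anchor("right")
  if (is.null(goal)) return(list(status = "no_goal_kmer"))

  max_steps <- (gap_end - gap_start) + start$off + goal$off + limits$F
  res <- cpp_path_search(start$kmer, goal$kmer, as_oracle(oracle),
                         as.integer(limits$B), as.integer(limits$P),
                         as.integer(max_steps))
  if (res$status != "ok") return(list(status = res$status))
  cons <- consensus_paths(res$paths)
  if (cons$status != "ok") return(list(status = "ambiguous"))
  # splice the full start-kmer..goal-kmer path over its scaffold span; a path
  # shorter than 2k means the flanking contigs truly overlap (negative gap)
  # and the overlap collapses naturally
  list(status = "closed",
       interval = c(gap_start - start$off - k, gap_end + goal$off + k),
       fill = cons$fill)
}

# replace scaffold[interval) (0-based half-open) with `fill`
splice_fill <- function(scaffold, interval, fill) {
  paste0(substr(scaffold, 1, interval[1]), fill,
         substr(scaffold, interval[2] + 1, nchar(scaffold)))
}

#' Fill one scaffold gap by bounded path search over a descending k sweep
#'
#' For each k in the sweep a Bloom filter is built from the read set and a
#' depth-first bounded path search is run from the k-mer left of the gap to
#' the k-mer right of it (anchors slide outward when absent from the filter).
#' A unique start-to-goal path closes the gap; 2..P equal-length paths with
#' pairwise identity of at least 95% close it with their column-majority
#' consensus; anything else records a failure status for that k. The first
#' successful k wins and the remaining sweep is skipped.
#'
#' @param scaffold Character scalar with `N` gaps.
#' @param gap One row of [find_gaps()] (or a list with `start`, `end`).
#' @param reads Read-pair tibble (or character vector of sequences).
#' @param sweep Descending k values (default [default_k_sweep()]).
#' @param limits A [path_limits()] object.
#' @param fpr Bloom filter target false-positive rate (default 0.001).
#' @return A `gap_fill_result`: list with `status` (`closed`,
#'   `no_start_kmer`, `no_goal_kmer`, `branch_limit`, `path_limit`,
#'   `no_path` or `ambiguous`), `k_used`, `fill`, `interval` and the per-k
#'   status tibble `per_k`. Overall failure status is the last attempted k's
#'   status.
#' @export
fill_gap <- function(scaffold, gap, reads, sweep = default_k_sweep(),
                     limits = path_limits(), fpr = 0.001) {
  if (any(diff(sweep) >= 0)) {
    stopf("invalid configuration: field 'sweep' must be strictly decreasing")
  }
  seqs <- as_sequences(reads)
  per_k <- list()
  result <- NULL
  for (k in sweep) {
    if (length(seqs) == 0 || max(nchar(seqs)) < k) next
    oracle <- suppressWarnings(build_bloom(seqs, k = k, target_fpr = fpr))
    att <- attempt_gap(scaffold, gap$start, gap$end, oracle, k, limits)
    per_k[[length(per_k) + 1L]] <- tibble(k = k, status = att$status)
    if (att$status == "closed") {
      result <- c(att, list(k_used = k))
      break
    }
    # an ambiguous outcome is definitive: lowering k only adds paths
    if (att$status == "ambiguous") break
  }
  per_k <- if (length(per_k)) bind_rows(per_k) else tibble(k = integer(0), status = character(0))
  if (is.null(result)) {
    status <- if (nrow(per_k)) per_k$status[nrow(per_k)] else "no_start_kmer"
    result <- list(status = status, k_used = NA_integer_, fill = NULL,
                   interval = NULL)
  }
  structure(c(result, list(gap = list(start = gap$start, end = gap$end),
                           per_k = per_k)),
            class = "gap_fill_result")
}

#' @export
print.gap_fill_result <- function(x, ...) {
  cat(sprintf("<gap_fill_result> [%d,%d) %s%s\n", x$gap$start, x$gap$end,
              x$status,
              if (x$status == "closed") sprintf(" at k = %d (%d bp fill)",
                                                x$k_used, nchar(x$fill)) else ""))
  invisible(x)
}

#' Enrich read pairs for one gap locus using a related reference
#'
#' The gap's two flanks are anchored onto the reference by their first unique
#' exact k-mer seed (ungapped projection); the reference interval strictly
#' between the anchored flank edges, widened by `pad` on each side, is
#' extracted; a Bloom filter over that interval then classifies the read bin,
#' keeping pairs that look like the gap locus.
#'
#' @param scaffold Scaffold sequence.
#' @param gap One row of [find_gaps()].
#' @param reference Related-species reference sequence.
#' @param reads Read-pair tibble to filter.
#' @param flank Flanking sequence taken on each side of the gap (default 500).
#' @param pad Reference padding around the unaligned interval (default 24).
#' @param k Bloom/seed k-mer length (default 25).
#' @param fpr Bloom target false-positive rate (default 0.001).
#' @param min_share Classification threshold (default 0.15).
#' @return List with `status` (`"ok"` or `"unanchored"`), `reads` (kept
#'   pairs, `NULL` when unanchored) and `interval` (0-based half-open
#'   reference interval extracted).
#' @export
enrich_reads_for_gap <- function(scaffold, gap, reference, reads, flank = 500,
                                 pad = 24, k = 25, fpr = 0.001,
                                 min_share = 0.15) {
  L <- nchar(scaffold)
  lf_start <- max(0L, gap$start - flank)
  left_seq <- substr(scaffold, lf_start + 1, gap$start)
  rt_end <- min(L, gap$end + flank)
  right_seq <- substr(scaffold, gap$end + 1, rt_end)
  a_left <- cpp_anchor_flank(reference, left_seq, as.integer(k))
  a_right <- cpp_anchor_flank(reference, right_seq, as.integer(k))
  if (a_left[2] == 0L || a_right[2] == 0L || a_left[2] != a_right[2]) {
    return(list(status = "unanchored", reads = NULL, interval = NULL))
  }
  strand <- a_left[2]
  if (strand == 1L) {
    lo <- a_left[1] + nchar(left_seq) # ref coord just right of left flank
    hi <- a_right[1]
  } else {
    lo <- a_right[1] + nchar(right_seq)
    hi <- a_left[1]
  }
  if (hi < lo) return(list(status = "unanchored", reads = NULL, interval = NULL))
  lo2 <- max(0L, lo - pad)
  hi2 <- min(nchar(reference), hi + pad)
  extracted <- substr(reference, lo2 + 1, hi2)
  if (nchar(extracted) < k) {
    return(list(status = "unanchored", reads = NULL,
                interval = c(lo2, hi2)))
  }
  bf <- build_bloom(extracted, k = k, target_fpr = fpr)
  kept <- classify_reads(reads, bf, min_share = min_share)
  list(status = "ok", reads = kept, interval = c(lo2, hi2))
}

#' Fill all scaffold gaps over successive read bins
#'
#' Round 1 attempts every gap with the first (most selective) bin unenriched,
#' sharing one Bloom filter per sweep k across gaps. Each subsequent round
#' takes the next bin and, when a reference is supplied, enriches reads per
#' remaining gap with [enrich_reads_for_gap()] before filling (falling back
#' to the unenriched bin when a gap cannot be anchored). Closed gaps are
#' spliced in after each round and never reopen; flanking bases outside a
#' filled interval are untouched.
#'
#' @param scaffold Scaffold sequence with `N` gaps.
#' @param bins List of read-pair tibbles ordered from most to least
#'   selective; the first is also used for the unenriched round.
#' @param reference Optional related reference for per-gap enrichment.
#' @param sweep Descending k sweep (default [default_k_sweep()]).
#' @param limits A [path_limits()] object.
#' @param fpr Bloom target false-positive rate.
#' @param ... Passed to [enrich_reads_for_gap()] (`flank`, `pad`, `k`,
#'   `min_share`).
#' @return A `gap_fill_report`: list with `scaffold` (final sequence) and
#'   `results` (tibble: `round`, `bin`, `enriched`, `gap_start`, `gap_end`,
#'   `status`, `k_used`).
#' @export
fill_all_gaps <- function(scaffold, bins, reference = NULL,
                          sweep = default_k_sweep(), limits = path_limits(),
                          fpr = 0.001, ...) {
  results <- list()
  record <- function(round, bin, enriched, gs, ge, status, k_used) {
    results[[length(results) + 1L]] <<- tibble(
      round = round, bin = bin, enriched = enriched, gap_start = gs,
      gap_end = ge, status = status, k_used = k_used
    )
  }
  n_rounds <- if (length(bins)) length(bins) + 1L else 0L
  for (round in seq_len(n_rounds)) {
    gaps <- find_gaps(scaffold)
    if (nrow(gaps) == 0) break
    bin_i <- max(1L, round - 1L)
    bin <- bins[[bin_i]]
    enriched <- round > 1L && !is.null(reference)
    fills <- list()
    if (!enriched) {
      # shared Bloom filter per k across all open gaps
      open <- rep(TRUE, nrow(gaps))
      seqs <- as_sequences(bin)
      last_status <- rep("not_attempted", nrow(gaps))
      k_used <- rep(NA_integer_, nrow(gaps))
      halted <- rep(FALSE, nrow(gaps))
      for (k in sweep) {
        if (!any(open & !halted)) break
        if (length(seqs) == 0 || max(nchar(seqs)) < k) next
        oracle <- suppressWarnings(build_bloom(seqs, k = k, target_fpr = fpr))
        for (gi in which(open & !halted)) {
          att <- attempt_gap(scaffold, gaps$start[gi], gaps$end[gi], oracle,
                             k, limits)
          last_status[gi] <- att$status
          if (att$status == "closed") {
            open[gi] <- FALSE
            k_used[gi] <- k
            fills[[length(fills) + 1L]] <- att
          } else if (att$status == "ambiguous") {
            # definitive: lowering k only adds paths
            halted[gi] <- TRUE
          }
        }
      }
      for (gi in seq_len(nrow(gaps))) {
        record(round, bin_i, FALSE, gaps$start[gi], gaps$end[gi],
               if (open[gi]) last_status[gi] else "closed", k_used[gi])
      }
    } else {
      for (gi in seq_len(nrow(gaps))) {
        g <- list(start = gaps$start[gi], end = gaps$end[gi])
        er <- enrich_reads_for_gap(scaffold, g, reference, bin, fpr = fpr, ...)
        use <- if (er$status == "ok" && nrow(er$reads) > 0) er$reads else bin
        fr <- fill_gap(scaffold, g, use, sweep = sweep, limits = limits,
                       fpr = fpr)
        record(round, bin_i, er$status == "ok", g$start, g$end, fr$status,
               fr$k_used)
        if (fr$status == "closed") {
          fills[[length(fills) + 1L]] <- fr
        }
      }
    }
    # splice right-to-left so earlier intervals stay valid
    if (length(fills)) {
      ord <- order(vapply(fills, function(f) f$interval[1], 0), decreasing = TRUE)
      for (f in fills[ord]) {
        scaffold <- splice_fill(scaffold, f$interval, f$fill)
      }
    }
  }
  results <- if (length(results)) bind_rows(results) else
    tibble(round = integer(0), bin = integer(0), enriched = logical(0),
           gap_start = integer(0), gap_end = integer(0), status = character(0),
           k_used = integer(0))
  structure(list(scaffold = scaffold, results = results),
            class = "gap_fill_report")
}

#' @export
print.gap_fill_report <- function(x, ...) {
  n_open <- nrow(find_gaps(x$scaffold))
  cat(sprintf("<gap_fill_report> %d attempt(s) over %d round(s); %d gap(s) remain\n",
              nrow(x$results), length(unique(x$results$round)), n_open))
  invisible(x)
}

#' Mask a scaffold region with Ns
#'
#' Replaces the bases of a 0-based half-open interval with `N`, e.g. to force
#' the gap filler to restart from a k-mer upstream of a suspect region.
#' Masking adjacent to an existing `N` run simply extends that gap.
#'
#' @param scaffold Scaffold sequence.
#' @param start,end 0-based half-open interval.
#' @return The masked sequence.
#' @export
mask_region <- function(scaffold, start, end) {
  L <- nchar(scaffold)
  if (start < 0 || end > L || start > end) {
    stopf("mask interval [%s,%s) out of bounds for a %d bp sequence",
          format(start), format(end), L)
  }
  if (end == start) return(scaffold)
  paste0(substr(scaffold, 1, start), strrep("N", end - start),
         substr(scaffold, end + 1, L))
}

#' Join scaffold ends into a circular sequence
#'
#' Treats the two scaffold ends as a long-insert "read pair": the last
#' `end_len` bases and the reverse complement of the first `end_len` bases.
#' The same bounded path search as gap filling is run from the tail k-mer to
#' the head k-mer through a Bloom filter of the reads, within `max_fragment`
#' extensions. A unique (or consensus-resolvable) connecting path appends the
#' inter-end sequence and marks the genome circular.
#'
#' @param scaffold Gap-free scaffold sequence.
#' @param reads Read-pair tibble (or sequences) covering the junction locus.
#' @param k Junction k-mer length (default 80).
#' @param max_fragment Maximum joined fragment span in bp (default 3500).
#' @param end_len End region length in bp (default 200).
#' @param limits A [path_limits()] object.
#' @param fpr Bloom target false-positive rate.
#' @return List with `sequence`, `circular` (logical) and `status`
#'   (`"circular"` or `"not_circularizable"`).
#' @export
join_ends <- function(scaffold, reads, k = 80, max_fragment = 3500,
                      end_len = 200, limits = path_limits(), fpr = 0.001) {
  if (grepl("N", scaffold, fixed = TRUE)) {
    stopf("scaffold still contains gaps; fill them before circularizing")
  }
  L <- nchar(scaffold)
  seqs <- as_sequences(reads)
  oracle <- suppressWarnings(build_bloom(seqs, k = k, target_fpr = fpr))
  slide <- function(side) {
    for (off in 0:(end_len - k)) {
      kmer <- if (side == "tail") substr(scaffold, L - off - k + 1, L - off)
      else substr(scaffold, off + 1, off + k)
      if (oracle_has(oracle, kmer)) return(list(kmer = kmer, off = off))
    }
    NULL
  }
  tail_a <- slide("tail")
  head_a <- slide("head")
  if (is.null(tail_a) || is.null(head_a)) {
    return(list(sequence = scaffold, circular = FALSE,
                status = "not_circularizable"))
  }
  res <- cpp_path_search(tail_a$kmer, head_a$kmer, as_oracle(oracle),
                         as.integer(limits$B), as.integer(limits$P),
                         as.integer(max_fragment))
  if (res$status != "ok") {
    return(list(sequence = scaffold, circular = FALSE,
                status = "not_circularizable"))
  }
  cons <- consensus_paths(res$paths)
  if (cons$status != "ok") {
    return(list(sequence = scaffold, circular = FALSE,
                status = "not_circularizable"))
  }
  core <- substr(scaffold, head_a$off + 1, L - tail_a$off)
  plen <- nchar(cons$fill)
  circ <- if (plen >= 2 * k) {
    # append the inter-end sequence between tail and head k-mers
    paste0(core, substr(cons$fill, k + 1, plen - k))
  } else {
    # scaffold ends overlap on the circle by 2k - plen bases; trim the overlap
    substr(core, 1, nchar(core) - (2 * k - plen))
  }
  list(sequence = circ, circular = TRUE, status = "circular")
}

# two-pointer least-rotation (Booth-style), O(n)
least_rotation <- function(s) {
  n <- nchar(s)
  ss <- strsplit(paste0(s, s), "", fixed = TRUE)[[1]]
  i <- 0; j <- 1; k <- 0
  while (i < n && j < n && k < n) {
    a <- ss[i + k + 1]; b <- ss[j + k + 1]
    if (a == b) {
      k <- k + 1
    } else if (a > b) {
      i <- i + k + 1
      if (i == j) i <- i + 1
      k <- 0
    } else {
      j <- j + k + 1
      if (j == i) j <- j + 1
      k <- 0
    }
  }
  start <- min(i, j)
  paste(ss[(start + 1):(start + n)], collapse = "")
}

#' Canonical rotation of a circular sequence
#'
#' Rotates (and complements when needed) a circular sequence so that the
#' k-mer matching the reference's first k-mer sits at position 0; when no
#' unique anchor exists, falls back to the lexicographically minimal rotation
#' over both strands. Any rotation or strand of the same circle therefore
#' maps to one representative.
#'
#' @param seq Circular sequence (character scalar).
#' @param reference Optional reference whose first k bases anchor position 0.
#' @param k Anchor length (default 31).
#' @return The canonical representative.
#' @export
canonical_rotation <- function(seq, reference = NULL, k = 31) {
  rotate_to <- function(s, pos) { # 0-based
    if (pos == 0) s else paste0(substr(s, pos + 1, nchar(s)), substr(s, 1, pos))
  }
  if (!is.null(reference) && nchar(reference) >= k) {
    anchor <- substr(reference, 1, k)
    for (s in c(seq, revcomp(seq))) {
      doubled <- paste0(s, substr(s, 1, k - 1)) # anchor may span the origin
      hits <- gregexpr(anchor, doubled, fixed = TRUE)[[1]]
      hits <- hits[hits != -1 & hits <= nchar(s)]
      if (length(hits) == 1) return(rotate_to(s, hits[1] - 1L))
    }
  }
  min(least_rotation(seq), least_rotation(revcomp(seq)))
}
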