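other_end <- function(e) ifelse(e == "head", "tail", "head")

#' Extract paired k-mers from a reference at a fixed separation
#'
#' Takes a k-mer pair at every `step` positions of the reference: the left
#' k-mer at position `p` and the right k-mer at `p + d` (start-to-start
#' separation `d`). These pairs act as long-range distance constraints when
#' ordering contigs against a related genome. Pairs in which either k-mer
#' occurs more than once in the reference (canonically) are dropped: a
#' repeated k-mer — e.g. from inside the reference's own inverted repeat —
#' cannot identify a locus and would vote for wrong-strand misjoins.
#'
#' @param reference Character scalar reference sequence.
#' @param k K-mer length (default 26).
#' @param d Start-to-start separation in bp.
#' @param step Position step (default 1: every position).
#' @return Tibble (`pos`, `left`, `right`, `d`); empty when the reference is
#'   shorter than `d + k`.
#' @export
extract_kmer_pairs <- function(reference, k = 26, d, step = 1) {
  L <- nchar(reference)
  if (L < d + k) {
    return(tibble(pos = integer(0), left = character(0),
                  right = character(0), d = integer(0)))
  }
  p <- seq(0L, L - d - k, by = step)
  out <- tibble(
    pos = p,
    left = substring(reference, p + 1L, p + k),
    right = substring(reference, p + d + 1L, p + d + k),
    d = as.integer(d)
  )
  all_k <- canonical_kmer(substring(reference, 1:(L - k + 1), k:L))
  dup <- unique(all_k[duplicated(all_k)])
  if (length(dup)) {
    out <- out[!(canonical_kmer(out$left) %in% dup) &
                 !(canonical_kmer(out$right) %in% dup), , drop = FALSE]
  }
  out
}

#' Collect contig-link evidence from reference k-mer pairs
#'
#' Each k-mer pair whose two members land in different contigs (only k-mers
#' occurring exactly once across all contigs, canonically, are used) casts one
#' vote for the implied junction between a contig end and another contig end,
#' with a gap estimate `d - (left k-mer to its contig's 3' end) - (right
#' contig's 5' end to right k-mer)`. Votes are aggregated into support counts.
#'
#' @param pairs Tibble from [extract_kmer_pairs()].
#' @param contigs Contig tibble (`id`, `sequence`) or named character vector.
#' @return Evidence tibble (`contig_a`, `end_a`, `contig_b`, `end_b`, `gap`,
#'   `support`), junctions normalised so `contig_a <= contig_b`.
#' @export
collect_links <- function(pairs, contigs) {
  ctg <- as_contigs(contigs)
  votes <- as_tibble(cpp_collect_links(unname(ctg), pairs$left, pairs$right,
                                       pairs$d))
  if (nrow(votes) == 0) {
    return(tibble(contig_a = character(0), end_a = character(0),
                  contig_b = character(0), end_b = character(0),
                  gap = numeric(0), support = integer(0)))
  }
  swap <- votes$a > votes$b
  votes[swap, c("a", "end_a", "b", "end_b")] <-
    votes[swap, c("b", "end_b", "a", "end_a")]
  votes %>%
    group_by(.data$a, .data$end_a, .data$b, .data$end_b) %>%
    summarise(gap = round(mean(.data$gap)), support = n(), .groups = "drop") %>%
    mutate(contig_a = names(ctg)[.data$a],
           end_a = c("head", "tail")[.data$end_a + 1L],
           contig_b = names(ctg)[.data$b],
           end_b = c("head", "tail")[.data$end_b + 1L]) %>%
    select("contig_a", "end_a", "contig_b", "end_b", "gap", "support") %>%
    arrange(desc(.data$support), abs(.data$gap), .data$contig_a, .data$end_a,
            .data$contig_b, .data$end_b)
}

as_contigs <- function(contigs) {
  if (is.data.frame(contigs)) {
    setNames(contigs$sequence, contigs$id)
  } else {
    if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
    contigs
  }
}

#' Greedy scaffold layout from link evidence
#'
#' Links below `min_support` are dropped; remaining links are accepted in
#' order of decreasing support (ties: smaller absolute gap estimate, then
#' lexicographic ids), each contig end taking at most one partner and
#' cycle-closing links being skipped — which breaks any cycle at its weakest
#' link. The result is deterministic regardless of input order.
#'
#' @param evidence Tibble from [collect_links()].
#' @param contig_ids All contig ids under layout (so unlinked contigs are
#'   reported as unplaced singletons).
#' @param min_support Minimum votes for a usable link (default 5).
#' @return A `scaffold_layout`: tibble (`scaffold_id`, `position`,
#'   `contig_id`, `orientation`, `gap_after`) with unlinked contigs in
#'   attribute `unplaced`.
#' @export
layout_scaffolds <- function(evidence, contig_ids, min_support = 5) {
  ev <- evidence %>%
    filter(.data$support >= min_support) %>%
    arrange(desc(.data$support), abs(.data$gap), .data$contig_a, .data$end_a,
            .data$contig_b, .data$end_b)

  parent <- setNames(seq_along(contig_ids), contig_ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  used <- character(0) # "id:end" keys
  links <- list()
  for (i in seq_len(nrow(ev))) {
    a <- ev$contig_a[i]; ea <- ev$end_a[i]
    b <- ev$contig_b[i]; eb <- ev$end_b[i]
    ka <- paste0(a, ":", ea); kb <- paste0(b, ":", eb)
    if (ka %in% used || kb %in% used) next
    ra <- find(which(contig_ids == a)); rb <- find(which(contig_ids == b))
    if (ra == rb) next # would close a cycle: break it here (weakest link)
    parent[ra] <- rb
    used <- c(used, ka, kb)
    links[[length(links) + 1L]] <- ev[i, ]
  }
  links <- if (length(links)) bind_rows(links) else ev[0, ]

  # adjacency keyed by contig end
  adj <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(links))) {
    assign(paste0(links$contig_a[i], ":", links$end_a[i]),
           list(id = links$contig_b[i], end = links$end_b[i], gap = links$gap[i]),
           envir = adj)
    assign(paste0(links$contig_b[i], ":", links$end_b[i]),
           list(id = links$contig_a[i], end = links$end_a[i], gap = links$gap[i]),
           envir = adj)
  }
  linked <- unique(c(links$contig_a, links$contig_b))
  has_link <- function(id, end) exists(paste0(id, ":", end), envir = adj)

  placed <- character(0)
  rows <- list()
  scaf <- 0L
  for (start in sort(linked)) {
    if (start %in% placed) next
    free_ends <- c("head", "tail")[!c(has_link(start, "head"), has_link(start, "tail"))]
    if (length(free_ends) == 0) next # interior of a chain; reached later
    enter <- sort(free_ends)[1]
    scaf <- scaf + 1L
    cur <- start
    e_in <- enter
    pos <- 0L
    repeat {
      pos <- pos + 1L
      orientation <- if (e_in == "head") "+" else "-"
      e_out <- other_end(e_in)
      nxt <- if (has_link(cur, e_out)) get(paste0(cur, ":", e_out), envir = adj) else NULL
      rows[[length(rows) + 1L]] <- tibble(
        scaffold_id = sprintf("scaffold%03d", scaf), position = pos,
        contig_id = cur, orientation = orientation,
        gap_after = if (is.null(nxt)) NA_real_ else nxt$gap
      )
      placed <- c(placed, cur)
      if (is.null(nxt)) break
      cur <- nxt$id
      e_in <- nxt$end
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(scaffold_id = character(0), position = integer(0),
           contig_id = character(0), orientation = character(0),
           gap_after = numeric(0))
  attr(out, "unplaced") <- setdiff(contig_ids, out$contig_id)
  class(out) <- c("scaffold_layout", class(out))
  out
}

#' Render a scaffold layout to sequences
#'
#' Oriented contig sequences are joined with `N` runs: a gap estimate of at
#' least 1 renders that many `N`s, a zero or negative estimate renders a
#' single `N` (adjacent contigs are never overlapped or merged here; the gap
#' filler resolves the junction from reads). Unplaced contigs are emitted as
#' singleton scaffolds.
#'
#' @param layout A [layout_scaffolds()] result.
#' @param contigs Contig tibble or named character vector.
#' @return Tibble (`id`, `sequence`, `length`, `n_gaps`) with the constituent
#'   contig ids in the list column `contigs`.
#' @export
render_scaffolds <- function(layout, contigs) {
  ctg <- as_contigs(contigs)
  out <- list()
  for (sid in unique(layout$scaffold_id)) {
    part <- layout[layout$scaffold_id == sid, , drop = FALSE]
    part <- part[order(part$position), , drop = FALSE]
    pieces <- character(0)
    for (i in seq_len(nrow(part))) {
      s <- ctg[[part$contig_id[i]]]
      if (part$orientation[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (i < nrow(part)) {
        g <- part$gap_after[i]
        pieces <- c(pieces, strrep("N", max(1, g)))
      }
    }
    out[[sid]] <- list(sequence = paste(pieces, collapse = ""),
                       contigs = part$contig_id)
  }
  for (id in attr(layout, "unplaced")) {
    out[[id]] <- list(sequence = ctg[[id]], contigs = id)
  }
  tibble(
    id = names(out),
    sequence = vapply(out, `[[`, "", "sequence"),
    length = vapply(out, function(x) nchar(x$sequence), 0),
    n_gaps = vapply(out, function(x) {
      nrow(find_gaps(x$sequence))
    }, 0),
    contigs = lapply(out, `[[`, "contigs")
  )
}

#' Default distance schedule for iterative scaffolding
#'
#' Separations swept from 250 bp to 16 kb: step 250 up to 2 kb, step 500 up
#' to 9 kb, step 1000 up to 16 kb.
#'
#' @return Strictly increasing integer vector.
#' @export
default_link_schedule <- function() {
  c(seq(250L, 2000L, by = 250L), seq(2500L, 9000L, by = 500L),
    seq(10000L, 16000L, by = 1000L))
}

#' Iteratively scaffold contigs against a related reference
#'
#' Runs the paired-k-mer scaffolder once per separation in `schedule`
#' (strictly increasing), feeding the output sequences of each round in as
#' the input of the next, so tight adjacencies are resolved before
#' longer-range constraints are applied.
#'
#' @param contigs Contig tibble (`id`, `sequence`) or named character vector.
#' @param reference Related-species reference sequence (character scalar).
#' @param schedule Separation schedule (default [default_link_schedule()]).
#' @param k Pair k-mer length (default 26).
#' @param min_support Minimum link votes (default 5).
#' @param step Reference position step (default 1).
#' @return A `scaffold_set` tibble (`id`, `sequence`, `length`, `n_gaps`,
#'   `contigs`) where `contigs` lists the original constituent contig ids.
#' @export
iterate_distances <- function(contigs, reference, schedule = default_link_schedule(),
                              k = 26, min_support = 5, step = 1) {
  if (any(diff(schedule) <= 0)) {
    stopf("invalid configuration: field 'schedule' must be strictly increasing")
  }
  cur <- as_contigs(contigs)
  prov <- as.list(setNames(names(cur), names(cur)))
  for (d in schedule) {
    pairs <- extract_kmer_pairs(reference, k = k, d = d, step = step)
    if (nrow(pairs) == 0) next
    ev <- collect_links(pairs, cur)
    layout <- layout_scaffolds(ev, names(cur), min_support = min_support)
    rendered <- render_scaffolds(layout, cur)
    new_ids <- sprintf("s%05d_%03d", d, seq_len(nrow(rendered)))
    prov <- setNames(lapply(seq_len(nrow(rendered)), function(i) {
      unique(unlist(prov[rendered$contigs[[i]]], use.names = FALSE))
    }), new_ids)
    cur <- setNames(rendered$sequence, new_ids)
  }
  n <- length(cur)
  out <- tibble(
    id = sprintf("scaffold%03d", seq_len(n)),
    sequence = unname(cur),
    length = nchar(unname(cur)),
    n_gaps = vapply(unname(cur), function(s) nrow(find_gaps(s)), 0),
    contigs = unname(prov)
  ) %>% arrange(desc(.data$length))
  out$id <- sprintf("scaffold%03d", seq_len(n))
  class(out) <- c("scaffold_set", class(out))
  out
}

#' Pick the scaffold matching a reference
#'
#' Scores every scaffold by the number of its k-mers found in a Bloom filter
#' of the reference and returns the id of the best scorer — the analogue of
#' identifying the single on-target scaffold among many background scaffolds.
#'
#' @param scaffolds A `scaffold_set` tibble (or `id`/`sequence` tibble).
#' @param reference Reference sequence.
#' @param k K-mer length (default 26).
#' @return The best-matching scaffold id.
#' @export
pick_target_scaffold <- function(scaffolds, reference, k = 26) {
  bf <- build_bloom(reference, k = k, target_fpr = 1e-4)
  share <- cpp_bloom_share(bf$bits, bf$m, bf$h, bf$k, scaffolds$sequence)
  hits <- share * pmax(nchar(scaffolds$sequence) - k + 1, 0)
  scaffolds$id[which.max(hits)]
}
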