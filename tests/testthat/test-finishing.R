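test_that("gap finding reports maximal N runs left to right", {
  expect_identical(find_gaps("ACGNNNACG"),
                   tibble::tibble(start = 3L, end = 6L))
  expect_identical(nrow(find_gaps("ACGTACGT")), 0L)
  expect_identical(find_gaps("NNACGNN"),
                   tibble::tibble(start = c(0L, 5L), end = c(2L, 7L)))
})

test_that("masking replaces bases and merges with adjacent gaps", {
  s <- "ACGTACGTACGT"
  m <- mask_region(s, 5, 8)
  expect_identical(substr(m, 6, 8), "NNN")
  expect_identical(substr(m, 1, 5), substr(s, 1, 5))
  expect_identical(nchar(m), nchar(s))
  # masking flush against an existing run yields one merged gap
  s2 <- mask_region(mask_region(s, 5, 8), 8, 10)
  expect_identical(nrow(find_gaps(s2)), 1L)
  expect_identical(mask_region(s, 4, 4), s)
  expect_error(mask_region(s, -1, 3), "out of bounds")
})

test_that("a masked region is recovered base-perfect and flanks are preserved", {
  truth <- r_random_dna(3000, seed = 81)
  reads <- r_tile_reads(truth, read_len = 100, step = 3)
  scaffold <- mask_region(truth, 1400, 1600)
  gap <- find_gaps(scaffold)[1, ]
  res <- fill_gap(scaffold, gap, reads, sweep = c(90L, 70L, 50L))
  expect_s3_class(res, "gap_fill_result")
  expect_identical(res$status, "closed")
  expect_identical(res$k_used, 90L)
  healed <- plastidlinker:::splice_fill(scaffold, res$interval, res$fill)
  expect_identical(healed, truth)
  # flank preservation: bases outside the replaced interval untouched
  expect_identical(substr(healed, 1, res$interval[1]),
                   substr(scaffold, 1, res$interval[1]))

  # withholding the spanning reads leaves the gap open
  spanning <- vapply(reads, function(r) {
    p <- regexpr(r, truth, fixed = TRUE)
    p > 0 && p + 99 > 1350 && p < 1650
  }, TRUE)
  res2 <- fill_gap(scaffold, gap, reads[!spanning], sweep = c(90L, 70L, 50L))
  expect_false(res2$status == "closed")
  expect_true(all(res2$per_k$status != "closed"))
})

test_that("search limits produce the documented failure modes", {
  # branch-rich toy: three equal-length variants between shared flanks
  x <- r_random_dna(60, seed = 82)
  y <- r_random_dna(60, seed = 83)
  variants <- vapply(1:3, function(i) r_random_dna(30), "")
  reads <- paste0(x, variants, y)
  scaffold <- paste0(x, strrep("N", 30), y)
  gap <- find_gaps(scaffold)[1, ]
  # one 3-way branch point = 2 extra extensions, so B = 1 is exceeded
  strict <- fill_gap(scaffold, gap, reads, sweep = 25L,
                     limits = path_limits(B = 1, P = 20))
  expect_identical(strict$status, "branch_limit")
  capped <- fill_gap(scaffold, gap, reads, sweep = 25L,
                     limits = path_limits(B = 3000, P = 1))
  expect_identical(capped$status, "path_limit")
  open <- fill_gap(scaffold, gap, reads, sweep = 25L,
                   limits = path_limits(B = 3000, P = 20))
  expect_identical(open$status, "ambiguous") # three dissimilar variants

  # two near-identical equal-length paths resolve by column-majority consensus
  v1 <- r_random_dna(40, seed = 84)
  v2 <- v1
  substr(v2, 20, 20) <- if (substr(v1, 20, 20) == "A") "C" else "A"
  reads2 <- c(paste0(x, v1, y), paste0(x, v1, y), paste0(x, v2, y))
  res2 <- fill_gap(paste0(x, strrep("N", 40), y), find_gaps(paste0(x, strrep("N", 40), y))[1, ],
                   reads2, sweep = 25L)
  expect_identical(res2$status, "closed")

  # a gap at the sequence edge cannot anchor
  edge <- paste0(strrep("N", 10), r_random_dna(100, seed = 85))
  res3 <- fill_gap(edge, find_gaps(edge)[1, ], reads, sweep = 25L)
  expect_identical(res3$status, "no_start_kmer")
})

test_that("bounded search agrees with exhaustive enumeration on exact graphs", {
  plant_allele <- function(truth, positions) {
    allele <- truth
    for (p in positions) {
      cur <- substr(allele, p, p)
      substr(allele, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    allele
  }
  for (seed in c(91, 92, 93, 94)) {
    truth <- r_random_dna(300, seed = seed)
    # a second allele with three well-spaced variants: exactly 8 branch combos
    allele <- plant_allele(truth, c(80, 150, 220))
    g <- build_kmer_graph(c(truth, allele), k = 15, min_count = 1)
    tab <- kmer_graph_table(g)
    expect_lte(nrow(tab), 1000)
    start <- substr(truth, 1, 15)
    goal <- substr(truth, 286, 300)
    cpp <- plastidlinker:::cpp_path_search(start, goal, g$ptr, 3000L, 50L, 400L)
    expect_identical(cpp$status, "ok")
    expect_identical(sort(cpp$paths), r_all_paths(start, goal, tab$kmer, 400))
    expect_identical(length(cpp$paths), 8L)
  }
})

test_that("per-gap enrichment extracts the right reference interval", {
  truth <- r_random_dna(6000, seed = 95)
  ref <- mutate_reference(truth, 0.01, seed = 96)
  scaffold <- mask_region(truth, 2800, 3100)
  gap <- find_gaps(scaffold)[1, ]
  reads <- tibble::tibble(
    pair_id = sprintf("p%03d", 1:200),
    read1 = r_tile_reads(truth, 100, 30)[1:200],
    read2 = r_tile_reads(truth, 100, 30)[1:200]
  )
  er <- enrich_reads_for_gap(scaffold, gap, ref, reads)
  expect_identical(er$status, "ok")
  # extracted interval covers the masked locus, within pad + divergence slop
  expect_lte(er$interval[1], 2800)
  expect_gte(er$interval[2], 3100)
  expect_lte(er$interval[2] - er$interval[1], 301 + 2 * 24 + 10)
  # kept pairs look like the gap locus
  kept_pos <- vapply(er$reads$read1, function(r) {
    as.integer(regexpr(r, truth, fixed = TRUE))
  }, 0L)
  expect_true(all(kept_pos + 100 > 2700 & kept_pos < 3200))

  # an unrelated reference cannot anchor
  er2 <- enrich_reads_for_gap(scaffold, gap, r_random_dna(6000, seed = 97), reads)
  expect_identical(er2$status, "unanchored")
})

test_that("end joining closes a circle whose scaffold misses both end pieces", {
  circle <- r_random_dna(6000, seed = 98)
  # linearise at an arbitrary origin, then lose 40 bp at the 5' end and
  # 300 bp at the 3' end, so both end regions must be recovered from reads
  lin <- paste0(substr(circle, 2001, 6000), substr(circle, 1, 2000))
  scaffold <- substr(lin, 41, 5700)
  reads <- r_tile_reads(circle, 125, 3, circular = TRUE)
  jj <- join_ends(scaffold, reads, k = 80, max_fragment = 3500, end_len = 200)
  expect_identical(jj$status, "circular")
  expect_identical(nchar(jj$sequence), 6000L)
  cmp <- compare_to_truth(jj$sequence, circle, circular = TRUE)
  expect_true(cmp$exact)

  # one missing base is recovered as a 1 bp insertion
  scaffold1 <- substr(lin, 2, 6000)
  jj1 <- join_ends(scaffold1, reads, k = 80)
  expect_identical(nchar(jj1$sequence), 6000L)
  expect_true(compare_to_truth(jj1$sequence, circle)$exact)

  # withholding junction-spanning reads blocks circularization; the missing
  # inter-end region sits at circle coordinates [1701, 2040]
  starts <- seq(1, 6000, by = 3)
  keep <- !(starts <= 2090 & starts + 124 >= 1660)
  jj2 <- join_ends(scaffold, reads[keep], k = 80)
  expect_identical(jj2$status, "not_circularizable")
  expect_identical(jj2$sequence, scaffold)
})

test_that("canonical rotation is invariant to rotation and strand", {
  s <- r_random_dna(100, seed = 99)
  rots <- vapply(c(1, 11, 47, 80), function(p) {
    paste0(substr(s, p, 100), substr(s, 1, p - 1))
  }, "")
  canon <- canonical_rotation(s)
  for (r in rots) {
    expect_identical(canonical_rotation(r), canon)
    expect_identical(canonical_rotation(r_revcomp(r)), canon)
  }
  # brute-force oracle: minimum over all rotations of both strands
  all_rots <- c(vapply(1:100, function(p) paste0(substr(s, p, 100), substr(s, 1, p - 1)), ""),
                vapply(1:100, function(p) {
                  rc <- r_revcomp(s)
                  paste0(substr(rc, p, 100), substr(rc, 1, p - 1))
                }, ""))
  expect_identical(canon, min(all_rots))
  # with a reference anchor, the reference's own start lands at position 0
  expect_identical(canonical_rotation(rots[3], reference = s), s)
})
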