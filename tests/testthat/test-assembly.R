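test_that("quality trimming follows the running-sum argmax rule", {
  q37 <- strrep(intToUtf8(37 + 33), 50)
  q2 <- strrep(intToUtf8(2 + 33), 10)
  reads <- tibble::tibble(
    pair_id = c("keep", "tail", "junk"),
    read1 = strrep("A", c(50, 60, 50)),
    qual1 = c(q37, paste0(q37, q2), strrep(intToUtf8(2 + 33), 50)),
    read2 = strrep("C", 50),
    qual2 = q37
  )
  out <- trim_reads(reads, q = 15, min_len = 20)
  expect_identical(out$pair_id, c("keep", "tail"))
  expect_identical(nchar(out$read1), c(50L, 50L)) # 10 low-quality bases removed
  expect_identical(attr(out, "dropped_pairs"), 1L) # all-Q2 read dropped
  # malformed qualities are a record-level error
  bad <- reads[1, ]
  bad$qual1 <- "!!"
  expect_error(trim_reads(bad), "keep")
})

test_that("canonical k-mer counting collapses reverse complements", {
  g <- suppressWarnings(build_kmer_graph("ACGTACGT", k = 4, min_count = 1))
  tab <- kmer_graph_table(g)
  # 5 windows: ACGT CGTA GTAC TACG ACGT -> canonical ACGT:2, CGTA:2, GTAC:1
  expect_identical(tab$kmer, c("ACGT", "CGTA", "GTAC"))
  expect_identical(tab$count, c(2L, 2L, 1L))

  # adding reverse complements doubles counts, changes nothing else
  reads <- substring(r_random_dna(300, seed = 9), 1:271, 30:300)
  g1 <- build_kmer_graph(reads, k = 21, min_count = 1)
  g2 <- build_kmer_graph(c(reads, unname(r_revcomp(reads))), k = 21, min_count = 1)
  t1 <- kmer_graph_table(g1)
  t2 <- kmer_graph_table(g2)
  expect_identical(t1$kmer, t2$kmer)
  expect_identical(2L * t1$count, t2$count)

  # min_count filtering removes singletons
  g3 <- suppressWarnings(build_kmer_graph("ACGTACGTT", k = 8, min_count = 2))
  expect_identical(g3$n_vertices, 0)
  expect_warning(build_kmer_graph("ACGTACGT", k = 4, min_count = 1),
                 class = "plastidlinker_even_k")
  expect_error(build_kmer_graph("ACGT", k = 10), "k")
})

test_that("unitigs reproduce a unique linear sequence and stop at bubbles", {
  s <- r_random_dna(2000, seed = 17)
  g <- build_kmer_graph(s, k = 31, min_count = 1)
  ctg <- build_unitigs(g, min_len = 500)
  expect_identical(nrow(ctg), 1L)
  expect_true(ctg$sequence %in% c(s, unname(r_revcomp(s))))
  expect_equal(ctg$coverage, 1)

  # bubble: shared flanks, two variant middles -> no contig spans the bubble
  x <- r_random_dna(80, seed = 21)
  y <- r_random_dna(80, seed = 22)
  a <- r_random_dna(40, seed = 23)
  b <- r_random_dna(40, seed = 24)
  gb <- build_kmer_graph(c(paste0(x, a, y), paste0(x, b, y)), k = 21,
                         min_count = 1)
  ctgb <- build_unitigs(gb, min_len = 1)
  expect_gte(nrow(ctgb), 3L)
  spans <- vapply(ctgb$sequence, function(s2) {
    any(c(grepl(paste0(x, a, y), s2, fixed = TRUE),
          grepl(paste0(x, b, y), s2, fixed = TRUE),
          grepl(r_revcomp(paste0(x, a, y)), s2, fixed = TRUE),
          grepl(r_revcomp(paste0(x, b, y)), s2, fixed = TRUE)))
  }, TRUE)
  expect_false(any(spans))
  # min_len larger than every path
  expect_identical(nrow(build_unitigs(gb, min_len = 10000)), 0L)
})

test_that("every contig k-mer exists in the graph and unitigs are idempotent", {
  reads <- r_tile_reads(r_random_dna(1500, seed = 31), read_len = 80, step = 7)
  g <- build_kmer_graph(reads, k = 25, min_count = 1)
  ctg <- build_unitigs(g, min_len = 1)
  for (s in ctg$sequence) {
    kmers <- substring(s, 1:(nchar(s) - 24), 25:nchar(s))
    expect_true(all(graph_contains(g, kmers)))
  }
  g2 <- build_kmer_graph(ctg$sequence, k = 25, min_count = 1)
  ctg2 <- build_unitigs(g2, min_len = 1)
  expect_identical(sort(ctg2$sequence), sort(ctg$sequence))
})

test_that("unitigs and blunt-end fraction match brute-force enumeration", {
  for (seed in c(101, 102, 103)) {
    seqs <- c(r_random_dna(220, seed = seed),
              r_random_dna(180, seed = seed + 50))
    reads <- unlist(lapply(seqs, r_tile_reads, read_len = 60, step = 9))
    g <- build_kmer_graph(reads, k = 21, min_count = 1)
    tab <- kmer_graph_table(g)
    expect_lte(nrow(tab), 500)
    expect_identical(sort(build_unitigs(g, min_len = 1)$sequence),
                     r_unitigs(tab$kmer, min_len = 1))
    expect_equal(blunt_end_fraction(g), r_blunt_fraction(tab$kmer))
  }
})

test_that("blunt-end fraction handles the boundary cases", {
  g1 <- build_kmer_graph("ACGTACG", k = 7, min_count = 1)
  expect_equal(blunt_end_fraction(g1), 1) # a lone vertex is blunt both ways

  # full circular coverage with all-distinct k-mers: no blunt vertices
  circle <- r_random_dna(400, seed = 55)
  reads <- r_tile_reads(circle, read_len = 60, step = 1, circular = TRUE)
  gc <- build_kmer_graph(reads, k = 31, min_count = 1)
  expect_equal(blunt_end_fraction(gc), 0)

  # unique linear sequence of L k-mers: exactly the two terminal vertices
  s <- r_random_dna(130, seed = 56)
  gl <- build_kmer_graph(s, k = 31, min_count = 1)
  L <- nchar(s) - 31 + 1
  expect_equal(blunt_end_fraction(gl), 2 / L)

  ge <- suppressWarnings(build_kmer_graph(character(0), k = 4, min_count = 1))
  expect_error(blunt_end_fraction(ge), "empty")
})
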