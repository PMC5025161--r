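test_that("filter sizing follows the standard formulas", {
  s <- r_random_dna(1024 + 24, seed = 61) # 1024 windows at k = 25
  bf <- build_bloom(s, k = 25, target_fpr = 0.001)
  n <- bf$n
  expect_equal(n, 1024)
  expect_equal(bf$m, ceiling(-n * log(0.001) / log(2)^2))
  expect_equal(bf$h, round((bf$m / n) * log(2)))
  expect_gte(bf$h, 1)
  # single k-length sequence
  one <- build_bloom("ACGTACGTACGTACGTACGTACGTA", k = 25, target_fpr = 0.01)
  expect_equal(one$n, 1)
  expect_true(bloom_contains(one, "ACGTACGTACGTACGTACGTACGTA"))
  expect_warning(build_bloom(c("ACGT", s), k = 25), "skipped")
})

test_that("membership is reverse-complement aware with no false negatives", {
  s <- r_random_dna(600, seed = 62)
  bf <- build_bloom(s, k = 25, target_fpr = 0.001)
  kmers <- substring(s, 1:(600 - 24), 25:600)
  expect_true(all(bloom_contains(bf, kmers)))
  expect_true(all(bloom_contains(bf, unname(r_revcomp(kmers)))))
})

test_that("empirical false-positive rate stays within twice the target", {
  set.seed(63)
  present <- vapply(1:2000, function(i) r_random_dna(25), "")
  bf <- build_bloom(present, k = 25, target_fpr = 0.001)
  probes <- vapply(1:10000, function(i) r_random_dna(25), "")
  canon <- canonical_kmer(probes)
  absent <- probes[!(canon %in% canonical_kmer(present))]
  fpr <- mean(bloom_contains(bf, absent))
  expect_lte(fpr, 0.002)
})

test_that("pair classification keeps locus reads and is monotone in the threshold", {
  locus <- r_random_dna(2000, seed = 64)
  bf <- build_bloom(locus, k = 25, target_fpr = 0.001)
  reads <- tibble::tibble(
    pair_id = sprintf("p%02d", 1:40),
    read1 = c(r_tile_reads(locus, 100, 100)[1:20],
              vapply(1:20, function(i) r_random_dna(100), "")),
    read2 = c(vapply(1:20, function(i) r_random_dna(100), ""),
              vapply(1:20, function(i) r_random_dna(100), ""))
  )
  # a read drawn verbatim from the source passes even at min_share = 1
  kept_strict <- classify_reads(reads, bf, min_share = 1)
  expect_setequal(kept_strict$pair_id, sprintf("p%02d", 1:20))
  # random pairs are dropped at min_share = 0.5
  kept_half <- classify_reads(reads, bf, min_share = 0.5)
  expect_setequal(kept_half$pair_id, sprintf("p%02d", 1:20))
  # min_share = 0 keeps everything, and higher thresholds give subsets
  expect_identical(nrow(classify_reads(reads, bf, min_share = 0)), 40L)
  prev <- reads$pair_id
  for (ms in c(0.1, 0.4, 0.8, 1)) {
    cur <- classify_reads(reads, bf, min_share = ms)$pair_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("bloom filters serialise losslessly", {
  s <- r_random_dna(400, seed = 65)
  bf <- build_bloom(s, k = 21, target_fpr = 0.01)
  path <- tempfile(fileext = ".bloom")
  on.exit(unlink(path))
  write_bloom(bf, path)
  bf2 <- read_bloom(path)
  expect_identical(bf2$bits, bf$bits)
  expect_equal(bf2[c("k", "m", "h", "n")], bf[c("k", "m", "h", "n")])
  kmers <- substring(s, 1:100, 21:120)
  expect_identical(bloom_contains(bf2, kmers), bloom_contains(bf, kmers))
})
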