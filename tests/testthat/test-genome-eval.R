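test_that("composition percentages use unambiguous bases only", {
  r <- composition("ACGT")
  expect_equal(unlist(r[c("a", "c", "g", "t")]), c(a = 25, c = 25, g = 25, t = 25))
  expect_equal(r$gc, 50)
  r2 <- composition("AANA")
  expect_equal(r2$a, 100)
  expect_equal(r2$length, 4)
  expect_equal(r2$denominator, 3)
  # conservation on arbitrary sequence
  r3 <- composition(r_random_dna(5000, seed = 101))
  expect_equal(r3$a + r3$c + r3$g + r3$t, 100)
  expect_equal(r3$gc, r3$c + r3$g)
  expect_error(composition(""), "empty")
})

test_that("ambiguity accounting conserves length and summarises runs", {
  r <- ambiguity_stats("ACNNNGT")
  expect_equal(r$ambiguous, 3)
  expect_equal(r$n_runs, 1)
  expect_equal(r$run_mean, 3)
  expect_equal(r$run_sd, 0) # single run: sample sd undefined, reported as 0
  r2 <- ambiguity_stats("ACGTACGT")
  expect_equal(r2$n_runs, 0)
  expect_equal(r2$ambiguous, 0)
  r3 <- ambiguity_stats("NNACGNNNNACGTN")
  expect_equal(r3$resolved + r3$ambiguous, r3$length)
  expect_equal(r3$n_runs, 3)
  expect_equal(r3$run_mean, mean(c(2, 4, 1)))
  expect_equal(r3$run_sd, sd(c(2, 4, 1)))
  # IUPAC codes beyond N count as ambiguous
  expect_equal(ambiguity_stats("ACGRYT")$ambiguous, 2)
})

test_that("exact-seed coverage behaves on tilings, empty input and supersets", {
  ref <- r_random_dna(2000, seed = 102)
  reads <- r_tile_reads(ref, 100, 10)
  cov <- read_coverage(ref, reads)
  expect_equal(cov$fraction, 1)
  expect_identical(length(cov$depth), 2000L)
  cov0 <- read_coverage(ref, character(0))
  expect_equal(cov0$fraction, 0)
  # monotone in the read set
  half <- read_coverage(ref, reads[seq(1, length(reads), 4)])
  expect_gte(cov$fraction, half$fraction)
  expect_true(all(cov$depth >= half$depth))
  # reverse-complemented reads place identically
  cov_rc <- read_coverage(ref, unname(r_revcomp(reads)))
  expect_identical(cov_rc$depth, cov$depth)
})

test_that("inverted repeat detection merges substitution-split anchors", {
  base <- r_random_dna(3000, seed = 103)
  copy1 <- substr(base, 801, 920) # 120 bp
  copy2 <- r_revcomp(copy1)
  # plant mismatches at interior offsets 30/60/90 of the second copy
  for (p in c(30, 60, 90)) {
    cur <- substr(copy2, p, p)
    substr(copy2, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  g <- paste0(substr(base, 1, 920), substr(base, 921, 2200), copy2,
              substr(base, 2321, 3000))
  ir <- detect_inverted_repeat(g)
  expect_identical(nrow(ir), 1L)
  expect_equal(ir$length, 120)
  expect_equal(ir$substitutions, 3)
  expect_equal(ir$start1, 800)
  expect_equal(ir$start2, 2200)

  # perfect IR: single anchor, zero substitutions
  g0 <- paste0(substr(base, 1, 920), substr(base, 921, 2200), r_revcomp(copy1),
               substr(base, 2321, 3000))
  ir0 <- detect_inverted_repeat(g0)
  expect_equal(ir0$length, 120)
  expect_equal(ir0$substitutions, 0)

  # no repeat of anchor length: empty report
  expect_identical(nrow(detect_inverted_repeat(r_random_dna(2000, seed = 104))), 0L)

  # strand symmetry
  ir_rc <- detect_inverted_repeat(r_revcomp(g))
  expect_equal(ir_rc$length, ir$length)
  expect_equal(ir_rc$substitutions, ir$substitutions)
})

test_that("truth comparison is rotation- and strand-aware", {
  truth <- r_random_dna(500, seed = 105)
  rot <- paste0(substr(truth, 201, 500), substr(truth, 1, 200))
  expect_true(compare_to_truth(rot, truth, circular = TRUE)$exact)
  expect_true(compare_to_truth(r_revcomp(rot), truth, circular = TRUE)$exact)
  mut <- rot
  substr(mut, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(mut, 100, 100))[1]
  cmp <- compare_to_truth(mut, truth, circular = TRUE)
  expect_false(cmp$exact)
  expect_identical(cmp$length_diff, 0L)
  expect_identical(cmp$n_mismatch, 1L)
  cmp2 <- compare_to_truth(substr(truth, 1, 400), truth, circular = FALSE)
  expect_identical(cmp2$length_diff, -100L)
  expect_true(is.na(cmp2$n_mismatch))
})
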