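test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(ir_length = -1), "ir_length")
  expect_error(sim_config(error_rate = 2), "error_rate")
  expect_error(sim_config(ir_length = 10000, organelle_length = 30000), "ir_length")
  expect_error(sim_config(read_length = 500, frag_len_median = 400), "read_length")
})

test_that("planted inverted repeat has exactly the requested substitutions", {
  for (mm in c(0L, 3L)) {
    cfg <- sim_config(seed = 11, organelle_length = 6000, nuclear_length = 0,
                      ir_length = 200, ir_mismatches = mm, frag_len_median = 5000)
    refs <- generate_genomes(cfg)
    ir <- refs$ir_coords
    copy1 <- substr(refs$organelle, ir$start[1] + 1, ir$end[1])
    copy2 <- substr(refs$organelle, ir$start[2] + 1, ir$end[2])
    diffs <- sum(strsplit(copy1, "")[[1]] != strsplit(r_revcomp(copy2), "")[[1]])
    expect_identical(diffs, as.integer(mm))
    expect_true(ir$end[1] <= ir$start[2]) # copies disjoint
  }
})

test_that("generation and simulation are deterministic for a fixed seed", {
  cfg <- sim_config(seed = 5, organelle_length = 3000, nuclear_length = 20000,
                    ir_length = 100, total_pairs = 2000, barcode_pool = 100,
                    frag_len_median = 2500)
  r1 <- generate_genomes(cfg)
  r2 <- generate_genomes(cfg)
  expect_identical(r1$organelle, r2$organelle)
  expect_identical(r1$nuclear, r2$nuclear)
  s1 <- simulate_linked_reads(r1, cfg)
  s2 <- simulate_linked_reads(r2, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("pair conservation and truth plumbing hold", {
  cfg <- sim_config(seed = 2, organelle_length = 3000, nuclear_length = 0,
                    copy_ratio = 1, ir_length = 100, total_pairs = 3000,
                    barcode_pool = 100, frag_len_median = 2500)
  refs <- generate_genomes(cfg)
  sim <- simulate_linked_reads(refs, cfg)
  expect_identical(nrow(sim$reads), 3000L)
  expect_identical(nrow(sim$truth), 3000L)
  expect_identical(sim$reads$pair_id, sim$truth$pair_id)
  # nuclear_length = 0: every pair is organelle
  expect_true(all(sim$truth$source == "organelle"))
  # coordinates wrapped into the circular source
  expect_true(all(sim$truth$start1 >= 0 & sim$truth$start1 < 3000))
  expect_true(all(sim$truth$start2 >= 0 & sim$truth$start2 < 3000))
  expect_true(all(nchar(sim$reads$read1) == cfg$read_length))
})

test_that("per-index counts are overdispersed and reads really come from their locus", {
  fx <- small_sim()
  counts <- fx$counts
  expect_gt(var(counts$n_pairs), mean(counts$n_pairs))
  # spot-check truth coordinates: an error-free prefix of read1 should occur
  # at its recorded locus for forward-strand organelle pairs
  tr <- dplyr::filter(fx$truth, source == "organelle", strand == "+")[1:25, ]
  rd <- fx$reads[match(tr$pair_id, fx$reads$pair_id), ]
  circle <- paste0(fx$refs$organelle, substr(fx$refs$organelle, 1, 200))
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    expected <- substr(circle, tr$start1[i] + 1, tr$start1[i] + 40)
    mism <- sum(strsplit(expected, "")[[1]] !=
                  strsplit(substr(rd$read1[i], 1, 40), "")[[1]])
    mism <= 2 # tolerate sequencing errors
  }, TRUE)
  expect_true(all(hits))
})

test_that("high-multiplicity indices are enriched for organelle reads", {
  fx <- small_sim()
  thr <- threshold_for_top_fraction(fx$counts, 0.01)
  top <- bin_reads(fx$reads, fx$counts, thr)
  share_all <- mean(fx$truth$source == "organelle")
  share_top <- mean(fx$truth$source[fx$truth$pair_id %in% top$pair_id] == "organelle")
  expect_gt(share_top, share_all)
})

test_that("mutate_reference applies the requested divergence and nothing else", {
  g <- r_random_dna(100000, seed = 42)
  expect_identical(mutate_reference(g, 0, seed = 1), structure(g, indel_mode = FALSE),
                   ignore_attr = TRUE)
  m <- mutate_reference(g, 0.01, seed = 7)
  expect_identical(nchar(m), nchar(g))
  rate <- mean(strsplit(g, "")[[1]] != strsplit(m, "")[[1]])
  expect_gte(rate, 0.008) # binomial 99% band around 0.01 at n = 1e5
  expect_lte(rate, 0.012)
  m2 <- mutate_reference(g, 0.01, seed = 8)
  expect_false(identical(m, m2))
})

test_that("quality profile decays over the final cycles so trimming is exercised", {
  fx <- small_sim()
  q <- utf8ToInt(fx$reads$qual1[1]) - 33L
  expect_true(all(q[1:100] == 37))
  expect_lt(q[length(q)], 15)
})
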