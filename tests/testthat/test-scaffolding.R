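test_that("paired k-mer extraction counts and bounds are exact", {
  ref <- r_random_dna(100, seed = 71)
  pairs <- extract_kmer_pairs(ref, k = 26, d = 50)
  expect_identical(nrow(pairs), 25L) # positions 0..24 satisfy p + d + k <= 100
  expect_identical(pairs$left[1], substr(ref, 1, 26))
  expect_identical(pairs$right[1], substr(ref, 51, 76))
  expect_identical(nrow(extract_kmer_pairs(ref, k = 26, d = 100)), 0L)
})

test_that("link evidence recovers the exact gap on an error-free tiling", {
  ref <- r_random_dna(2000, seed = 72)
  contigs <- tibble::tibble(
    id = c("A", "B"),
    sequence = c(substr(ref, 1, 900), substr(ref, 1001, 2000))
  )
  pairs <- extract_kmer_pairs(ref, k = 26, d = 250)
  ev <- collect_links(pairs, contigs)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$contig_a, "A")
  expect_identical(ev$end_a, "tail")
  expect_identical(ev$contig_b, "B")
  expect_identical(ev$end_b, "head")
  expect_equal(ev$gap, 100)
  expect_gt(ev$support, 100)

  # reverse-complementing one contig flips its junction end, nothing else
  contigs_rc <- contigs
  contigs_rc$sequence[2] <- r_revcomp(contigs_rc$sequence[2])
  ev_rc <- collect_links(pairs, contigs_rc)
  expect_identical(ev_rc$end_b, "tail")
  expect_equal(ev_rc$gap, ev$gap)
  expect_identical(ev_rc$support, ev$support)

  # pairs from the reference and from its reverse complement imply the same
  # junction after orientation normalisation
  ev_ref_rc <- collect_links(extract_kmer_pairs(r_revcomp(ref), k = 26, d = 250),
                             contigs)
  expect_identical(ev_ref_rc$contig_a, ev$contig_a)
  expect_identical(ev_ref_rc$end_a, ev$end_a)
  expect_identical(ev_ref_rc$end_b, ev$end_b)
  expect_equal(ev_ref_rc$gap, ev$gap)

  # a contig sharing no k-mer with the reference contributes no links
  contigs3 <- dplyr::bind_rows(contigs,
                               tibble::tibble(id = "X",
                                              sequence = r_random_dna(800, seed = 73)))
  ev3 <- collect_links(pairs, contigs3)
  expect_false("X" %in% c(ev3$contig_a, ev3$contig_b))
})

test_that("greedy layout follows support, drops conflicts and is order-stable", {
  ev <- tibble::tibble(
    contig_a = c("A", "B", "A"),
    end_a = c("tail", "tail", "tail"),
    contig_b = c("B", "C", "C"),
    end_b = c("head", "head", "head"),
    gap = c(10, 20, 500),
    support = c(10L, 8L, 3L)
  )
  lay <- layout_scaffolds(ev, c("A", "B", "C"), min_support = 1)
  expect_identical(lay$contig_id, c("A", "B", "C"))
  expect_identical(lay$orientation, c("+", "+", "+"))
  expect_equal(lay$gap_after, c(10, 20, NA))
  # the A-C link lost: A's tail was taken by the higher-support A-B link
  # (and C's head by B-C), so a single chain results
  expect_identical(length(unique(lay$scaffold_id)), 1L)
  expect_identical(attr(lay, "unplaced"), character(0))

  # min_support filters evidence
  lay2 <- layout_scaffolds(ev, c("A", "B", "C"), min_support = 9)
  expect_identical(sort(attr(lay2, "unplaced")), "C")

  # permuting evidence rows changes nothing
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    expect_identical(layout_scaffolds(ev[perm, ], c("A", "B", "C"), min_support = 1),
                     lay)
  }
})

test_that("iterative scaffolding recovers reference order and duplicates nothing", {
  truth <- r_random_dna(12000, seed = 74)
  # contigs tiling the truth with gaps, some reversed, plus one background contig
  cuts <- list(c(1, 2400), c(2501, 4800), c(4901, 7600), c(7681, 9900),
               c(10001, 12000))
  contigs <- tibble::tibble(
    id = sprintf("c%d", seq_along(cuts)),
    sequence = vapply(cuts, function(x) substr(truth, x[1], x[2]), "")
  )
  contigs$sequence[c(2, 4)] <- unname(r_revcomp(contigs$sequence[c(2, 4)]))
  contigs <- dplyr::bind_rows(contigs,
                              tibble::tibble(id = "bg",
                                             sequence = r_random_dna(1500, seed = 75)))
  ref <- mutate_reference(truth, 0.01, seed = 76)
  scafs <- iterate_distances(contigs, ref,
                             schedule = c(seq(250, 2000, 250), 2500, 3000))
  # no contig duplicated; placed bases conserved
  all_members <- unlist(scafs$contigs)
  expect_identical(anyDuplicated(all_members), 0L)
  non_n <- sum(nchar(gsub("N", "", scafs$sequence, fixed = TRUE)))
  expect_identical(non_n, sum(nchar(contigs$sequence)))
  # the on-target scaffold holds all five truth contigs in truth order
  tid <- pick_target_scaffold(scafs, ref)
  members <- scafs$contigs[[which(scafs$id == tid)]]
  expect_setequal(members, sprintf("c%d", 1:5))
  # background contig stays an unplaced singleton
  expect_true("bg" %in% scafs$id[vapply(scafs$contigs, identical, TRUE, "bg")] ||
                any(vapply(scafs$contigs, identical, TRUE, "bg")))
  # orientation/order check: the rendered scaffold matches the truth after
  # replacing each estimated gap run with the true spacer
  target <- scafs$sequence[scafs$id == tid]
  stripped <- gsub("N+", "", target)
  truth_stripped <- paste(vapply(cuts, function(x) substr(truth, x[1], x[2]), ""),
                          collapse = "")
  expect_true(stripped %in% c(truth_stripped, r_revcomp(truth_stripped)))
})

test_that("a single-distance schedule equals one scaffolding pass", {
  truth <- r_random_dna(4000, seed = 77)
  contigs <- tibble::tibble(
    id = c("u", "v"),
    sequence = c(substr(truth, 1, 1800), substr(truth, 1901, 4000))
  )
  one <- iterate_distances(contigs, truth, schedule = 500)
  pairs <- extract_kmer_pairs(truth, k = 26, d = 500)
  lay <- layout_scaffolds(collect_links(pairs, contigs), contigs$id, min_support = 5)
  direct <- render_scaffolds(lay, contigs)
  expect_identical(unname(sort(one$sequence)), unname(sort(direct$sequence)))
  expect_error(iterate_distances(contigs, truth, schedule = c(500, 500)),
               "schedule")
})
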