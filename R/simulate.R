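#' Simulation configuration for linked-read libraries
#'
#' Bundles every knob of the synthetic linked-read generator: a circular
#' high-copy organelle genome with a planted two-copy inverted repeat, a
#' low-copy nuclear background, long fragments partitioned into barcoded
#' droplets with barcode reuse, overdispersed reads-per-index counts, and
#' paired 125 bp reads with substitution errors.
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param organelle_length Circular organelle genome length in bp.
#' @param nuclear_length Total nuclear background length in bp (0 disables it).
#' @param copy_ratio Organelle:nuclear genome-copy ratio (dimensionless).
#' @param ir_length Length of each inverted-repeat copy in bp.
#' @param ir_mismatches Number of substitutions between the two IR copies.
#' @param barcode_pool Number of distinct 14 bp index sequences available.
#' @param frag_len_median Median nuclear fragment length in bp (lognormal).
#' @param frag_len_sdlog Lognormal sdlog of nuclear fragment lengths.
#' @param frags_per_barcode_mean Mean fragments per barcode; the number of
#'   fragments simulated is `round(barcode_pool * frags_per_barcode_mean)`.
#' @param plastome_copies_per_gem Mean plastome copies in one partitioned
#'   organelle particle (a chloroplast carries its genome in many nucleoid
#'   copies, so a droplet that captures one receives several genome
#'   equivalents of template); per-particle copy number is
#'   `1 + Poisson(mean - 1)`.
#' @param reads_per_fragment_dispersion Gamma shape of the per-fragment yield
#'   multiplier; smaller values give wider per-index count dispersion.
#' @param total_pairs Exact number of read pairs emitted.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert (outer fragment span of a pair) mean and
#'   sd in bp.
#' @param error_rate Per-base substitution error probability.
#' @param n_barcode_rate Probability that an emitted index carries one
#'   ambiguous base (`N`).
#' @param related_divergence Per-base substitution rate used when deriving the
#'   related-species surrogate reference with [mutate_reference()].
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_genomes()], [simulate_linked_reads()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, organelle_length = 6000, nuclear_length = 50000,
#'                   total_pairs = 5000)
#' cfg$copy_ratio
sim_config <- function(seed = 1L,
                       organelle_length = 30000,
                       nuclear_length = 1e6,
                       copy_ratio = 200,
                       ir_length = 440,
                       ir_mismatches = 3,
                       barcode_pool = 5000,
                       frag_len_median = 20000,
                       frag_len_sdlog = 0.55,
                       frags_per_barcode_mean = 1.5,
                       plastome_copies_per_gem = 4,
                       reads_per_fragment_dispersion = 2,
                       total_pairs = 200000,
                       read_length = 125,
                       insert_mean = 400,
                       insert_sd = 50,
                       error_rate = 0.002,
                       n_barcode_rate = 0.001,
                       related_divergence = 0.01) {
  cfg <- list(
    seed = seed, organelle_length = organelle_length,
    nuclear_length = nuclear_length, copy_ratio = copy_ratio,
    ir_length = ir_length, ir_mismatches = ir_mismatches,
    barcode_pool = barcode_pool, frag_len_median = frag_len_median,
    frag_len_sdlog = frag_len_sdlog,
    frags_per_barcode_mean = frags_per_barcode_mean,
    plastome_copies_per_gem = plastome_copies_per_gem,
    reads_per_fragment_dispersion = reads_per_fragment_dispersion,
    total_pairs = total_pairs, read_length = read_length,
    insert_mean = insert_mean, insert_sd = insert_sd,
    error_rate = error_rate, n_barcode_rate = n_barcode_rate,
    related_divergence = related_divergence
  )
  check_scalar_number(cfg$seed, "seed")
  check_scalar_number(cfg$organelle_length, "organelle_length", min = 1)
  check_scalar_number(cfg$nuclear_length, "nuclear_length", min = 0)
  check_scalar_number(cfg$copy_ratio, "copy_ratio", min = 0)
  check_scalar_number(cfg$ir_length, "ir_length", min = 0)
  check_scalar_number(cfg$ir_mismatches, "ir_mismatches", min = 0)
  check_scalar_number(cfg$barcode_pool, "barcode_pool", min = 1)
  check_scalar_number(cfg$frag_len_median, "frag_len_median", min = 1)
  check_scalar_number(cfg$frag_len_sdlog, "frag_len_sdlog", min = 0)
  check_scalar_number(cfg$frags_per_barcode_mean, "frags_per_barcode_mean", min = 0)
  check_scalar_number(cfg$plastome_copies_per_gem, "plastome_copies_per_gem", min = 1)
  check_scalar_number(cfg$reads_per_fragment_dispersion,
                      "reads_per_fragment_dispersion", min = 1e-6)
  check_scalar_number(cfg$total_pairs, "total_pairs", min = 0)
  check_scalar_number(cfg$read_length, "read_length", min = 1)
  check_scalar_number(cfg$insert_mean, "insert_mean", min = 1)
  check_scalar_number(cfg$insert_sd, "insert_sd", min = 0)
  check_scalar_number(cfg$error_rate, "error_rate", min = 0, max = 1)
  check_scalar_number(cfg$n_barcode_rate, "n_barcode_rate", min = 0, max = 1)
  check_scalar_number(cfg$related_divergence, "related_divergence",
                      min = 0, max = 1)
  if (cfg$ir_length >= cfg$organelle_length / 4) {
    stopf("invalid configuration: field 'ir_length' must be < organelle_length/4")
  }
  if (cfg$ir_mismatches > cfg$ir_length) {
    stopf("invalid configuration: field 'ir_mismatches' must be <= ir_length")
  }
  if (cfg$read_length > cfg$frag_len_median) {
    stopf("invalid configuration: field 'read_length' must be <= frag_len_median")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Generate reference genomes with a planted inverted repeat
#'
#' Draws an i.i.d. uniform circular organelle genome and linear nuclear
#' background, then plants a two-copy inverted repeat on the organelle: the
#' second copy is the reverse complement of the first except at exactly
#' `ir_mismatches` positions. The copy placement follows the plastome-like
#' quadripartite layout (large single-copy, IR, small single-copy, IR).
#'
#' @param config A [sim_config()].
#' @return An object of class `reference_set`: list with elements `organelle`
#'   (character scalar), `nuclear` (character vector, possibly empty) and
#'   `ir_coords` (tibble with 0-based half-open `start`,`end` for both copies).
#' @export
generate_genomes <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config object")
  set.seed(derive_seed(config$seed, 1))
  org <- random_dna(config$organelle_length)
  L <- config$organelle_length
  irl <- config$ir_length
  ir_coords <- tibble(copy = integer(0), start = integer(0), end = integer(0))
  if (irl > 0) {
    a <- round(0.30 * L)
    b <- round(0.72 * L)
    copy1 <- substr(org, a + 1, a + irl)
    copy2 <- revcomp(copy1)
    if (config$ir_mismatches > 0) {
      pos <- sort(sample.int(irl, config$ir_mismatches))
      for (p in pos) {
        cur <- substr(copy2, p, p)
        substr(copy2, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
    substr(org, b + 1, b + irl) <- copy2
    ir_coords <- tibble(copy = 1:2, start = c(a, b), end = c(a + irl, b + irl))
  }
  nuc <- if (config$nuclear_length > 0) random_dna(config$nuclear_length) else character(0)
  structure(list(organelle = org, nuclear = nuc, ir_coords = ir_coords),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>\n")
  cat(sprintf("  organelle: %d bp (circular)\n", nchar(x$organelle)))
  cat(sprintf("  nuclear:   %s\n",
              if (length(x$nuclear)) paste0(sum(nchar(x$nuclear)), " bp") else "none"))
  if (nrow(x$ir_coords)) {
    cat(sprintf("  IR copies: [%d,%d) and [%d,%d)\n",
                x$ir_coords$start[1], x$ir_coords$end[1],
                x$ir_coords$start[2], x$ir_coords$end[2]))
  }
  invisible(x)
}

#' Derive a related-species surrogate reference
#'
#' Returns a copy of `genome` with i.i.d. substitutions at rate `divergence`
#' (no indels by default), emulating a related-species guide sequence. An
#' optional small-indel mode additionally applies short (1-3 bp) insertions
#' and deletions at one tenth of the substitution rate; its use is flagged in
#' the `indel_mode` attribute of the result.
#'
#' @param genome Character scalar DNA sequence.
#' @param divergence Substitution rate per base, in `[0, 0.1)`.
#' @param seed Integer seed.
#' @param indels Logical; also apply small indels (default `FALSE`).
#' @return Character scalar with attribute `indel_mode`.
#' @export
mutate_reference <- function(genome, divergence, seed = 1L, indels = FALSE) {
  if (divergence < 0 || divergence >= 0.1) {
    stopf("invalid configuration: field 'divergence' must be in [0, 0.1)")
  }
  set.seed(derive_seed(seed, 2))
  bases <- strsplit(genome, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < divergence)
  for (p in hit) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
  }
  if (indels && length(bases)) {
    indel_rate <- divergence / 10
    keep <- runif(length(bases)) >= indel_rate / 2
    bases <- bases[keep]
    nins <- rbinom(1, length(bases), indel_rate / 2)
    if (nins > 0) {
      at <- sample.int(length(bases), nins)
      ins <- vapply(sample(1:3, nins, replace = TRUE),
                    function(l) paste(sample(c("A", "C", "G", "T"), l, TRUE),
                                      collapse = ""), "")
      bases[at] <- paste0(bases[at], ins)
    }
  }
  out <- paste(bases, collapse = "")
  attr(out, "indel_mode") <- indels
  out
}

# constant Q37 with a linear decay to Q12 over the final 15 cycles
quality_profile <- function(read_length) {
  q <- rep(37L, read_length)
  ntail <- min(15L, read_length)
  q[(read_length - ntail + 1):read_length] <-
    as.integer(round(seq(37, 12, length.out = ntail)))
  intToUtf8(q + 33L)
}

#' Simulate barcoded linked reads
#'
#' Draws long fragments from the organelle and nuclear genomes (sampling
#' probability proportional to copy-ratio-weighted genome length), partitions
#' them into barcoded droplets with barcode reuse, and emits paired 125 bp
#' reads with substitution errors. An organelle "fragment" is an intact
#' multi-copy plastome particle (a captured chloroplast contributes several
#' circular genome equivalents of template), nuclear fragment lengths are
#' lognormal truncated to 1-100 kb, and per-fragment read yield is
#' gamma-Poisson with mean proportional to template length. Per-index counts
#' are therefore overdispersed and high-multiplicity indices are
#' systematically enriched for organelle reads — the property the binning
#' workflow exploits. Exactly `total_pairs` pairs are emitted together with one ground
#' truth row per pair.
#'
#' @param refs A [generate_genomes()] result.
#' @param config The matching [sim_config()].
#' @return List with elements `reads` (tibble: `pair_id`, `index`, `read1`,
#'   `qual1`, `read2`, `qual2`) and `truth` (tibble: `pair_id`, `source`,
#'   `fragment`, `barcode`, `start1`, `start2`, `strand`); `start1`/`start2`
#'   are 0-based forward-strand starts on the source (wrapped for the circular
#'   organelle), `strand` is the strand of read 1. The number of fragments
#'   that had to be resampled because they were shorter than a drawn insert is
#'   attached as attribute `n_insert_clamped` on `reads`.
#' @export
simulate_linked_reads <- function(refs, config) {
  if (!inherits(refs, "reference_set")) stopf("refs must be a reference_set")
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config object")
  set.seed(derive_seed(config$seed, 3))
  rl <- config$read_length
  have_nuc <- length(refs$nuclear) > 0 && config$nuclear_length > 0

  # barcode pool: distinct 14-mers
  pool <- character(0)
  while (length(pool) < config$barcode_pool) {
    need <- config$barcode_pool - length(pool)
    cand <- vapply(seq_len(need + 16L), function(i) {
      paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = "")
    }, "")
    pool <- unique(c(pool, cand))
  }
  pool <- pool[seq_len(config$barcode_pool)]

  n_frag <- max(1L, as.integer(round(config$barcode_pool * config$frags_per_barcode_mean)))
  w_org <- config$copy_ratio * config$organelle_length
  w_nuc <- if (have_nuc) config$nuclear_length else 0
  p_org <- if (w_org + w_nuc > 0) w_org / (w_org + w_nuc) else 1
  src <- ifelse(runif(n_frag) < p_org, 1L, 2L)
  if (!have_nuc) src[] <- 1L

  # fragment template lengths: an organelle "fragment" is a multi-copy
  # plastome particle (circular template of several genome equivalents);
  # nuclear fragments are sheared HMW DNA, lognormal truncated to 1-100 kb
  flen <- numeric(n_frag)
  n_org <- sum(src == 1L)
  copies <- 1 + stats::rpois(n_org, max(0, config$plastome_copies_per_gem - 1))
  flen[src == 1L] <- config$organelle_length * copies
  if (any(src == 2L)) {
    nn <- sum(src == 2L)
    ln <- rlnorm(nn, meanlog = log(config$frag_len_median),
                 sdlog = config$frag_len_sdlog)
    ln <- pmin(pmax(round(ln), 1000), 100000)
    ln <- pmin(ln, config$nuclear_length)
    flen[src == 2L] <- ln
  }
  fstart <- numeric(n_frag)
  fstart[src == 1L] <- floor(runif(sum(src == 1L)) * config$organelle_length)
  if (any(src == 2L)) {
    fstart[src == 2L] <- floor(runif(sum(src == 2L)) *
                                 (config$nuclear_length - flen[src == 2L] + 1))
  }
  fstrand <- sample(c(1L, -1L), n_frag, replace = TRUE)
  fbarcode <- pool[sample.int(config$barcode_pool, n_frag, replace = TRUE)]

  # per-fragment pair counts: multinomial with probabilities proportional to
  # length x gamma multiplier (gamma-Poisson given the total)
  gmult <- rgamma(n_frag, shape = config$reads_per_fragment_dispersion,
                  rate = config$reads_per_fragment_dispersion)
  wts <- flen * gmult
  counts <- as.vector(rmultinom(1, size = config$total_pairs, prob = wts))
  total <- sum(counts)
  fidx <- rep.int(seq_len(n_frag), counts)

  # insert lengths; fragments shorter than a drawn insert are redrawn (logged)
  ins <- round(rnorm(total, config$insert_mean, config$insert_sd))
  ins <- pmax(ins, rl)
  too_big <- ins > flen[fidx]
  n_clamped <- 0L
  iter <- 0L
  while (any(too_big) && iter < 100L) {
    ins[too_big] <- pmax(round(rnorm(sum(too_big), config$insert_mean,
                                     config$insert_sd)), rl)
    too_big <- ins > flen[fidx]
    iter <- iter + 1L
  }
  if (any(too_big)) {
    n_clamped <- sum(too_big)
    ins[too_big] <- flen[fidx][too_big]
  }

  offset <- floor(runif(total) * (flen[fidx] - ins + 1))

  # genome-space coordinates of both reads (0-based forward-strand starts)
  fs <- fstart[fidx]
  fl <- flen[fidx]
  fstr <- fstrand[fidx]
  srcp <- src[fidx]
  circ <- srcp == 1L
  glen <- ifelse(circ, config$organelle_length, config$nuclear_length)

  # fragment-space read intervals: read1 = [o, o+rl), read2 = [o+ins-rl, o+ins)
  r1_off <- offset
  r2_off <- offset + ins - rl
  # map fragment offset -> genome forward coordinate of the window start
  frag_to_genome <- function(off) {
    fwd <- fs + off
    rev <- fs + fl - off - rl
    start <- ifelse(fstr == 1L, fwd, rev)
    ifelse(circ, start %% glen, start)
  }
  g1 <- frag_to_genome(r1_off)
  g2 <- frag_to_genome(r2_off)
  # read1 is spelled in fragment orientation; read2 reverse of it
  rc1 <- fstr == -1L
  rc2 <- fstr == 1L

  genomes <- c(refs$organelle,
               if (have_nuc) refs$nuclear[1] else "A")
  read1 <- cpp_extract_reads(genomes, srcp, g1, rep.int(rl, total), rc1,
                             c(TRUE, FALSE), config$error_rate)
  read2 <- cpp_extract_reads(genomes, srcp, g2, rep.int(rl, total), rc2,
                             c(TRUE, FALSE), config$error_rate)

  # emitted index: occasionally one position is an ambiguous base
  emitted <- fbarcode[fidx]
  amb <- which(runif(total) < config$n_barcode_rate)
  if (length(amb)) {
    at <- sample.int(14L, length(amb), replace = TRUE)
    emitted[amb] <- vapply(seq_along(amb), function(i) {
      s <- emitted[amb[i]]
      substr(s, at[i], at[i]) <- "N"
      s
    }, "")
  }

  ord <- sample.int(total)
  pair_id <- sprintf("pair%07d", seq_len(total))
  qual <- quality_profile(rl)
  reads <- tibble(
    pair_id = pair_id,
    index = emitted[ord],
    read1 = read1[ord], qual1 = qual,
    read2 = read2[ord], qual2 = qual
  )
  truth <- tibble(
    pair_id = pair_id,
    source = c("organelle", "nuclear")[srcp[ord]],
    fragment = fidx[ord],
    barcode = fbarcode[fidx][ord],
    start1 = g1[ord],
    start2 = g2[ord],
    strand = ifelse(rc1[ord], "-", "+")
  )
  attr(reads, "n_insert_clamped") <- n_clamped
  list(reads = reads, truth = truth)
}
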