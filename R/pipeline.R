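#' Pipeline run configuration
#'
#' Bundles every stage parameter of the end-to-end workflow: input (simulation
#' config or external FASTQ paths), bin selection, assembly, reference
#' scaffolding, gap-fill sweep and limits, circularization, and output.
#'
#' @param seed Integer master seed; per-stage seeds derive from it.
#' @param sim A [sim_config()] for simulated input, or `NULL` when reading
#'   external FASTQ (the simulation seed is overridden by `seed`).
#' @param fastq1,fastq2 External paired FASTQ paths (used when `sim` is
#'   `NULL`).
#' @param reference Related-species reference: a sequence string, a FASTA
#'   path, or `NULL` to derive a surrogate from the simulated organelle with
#'   [mutate_reference()].
#' @param bin_fractions Decreasing target top-fractions of read pairs for the
#'   multiplicity bins, least selective first (default `c(0.35, 0.10, 0.03)`,
#'   chosen so that at desk-scale library sizes the most selective bin still
#'   carries assembly-grade organelle depth); thresholds are derived per
#'   library with [threshold_for_top_fraction()].
#' @param bin_thresholds Explicit increasing pair-count thresholds; overrides
#'   `bin_fractions`.
#' @param trim_q Quality-trim threshold (default 15).
#' @param assembly_k,assembly_min_count,assembly_min_len De Bruijn assembly
#'   parameters (defaults 48, 2, 500).
#' @param scaffold_k,scaffold_min_support Paired-k-mer scaffolding parameters
#'   (defaults 26, 5).
#' @param schedule Scaffolding separation schedule
#'   (default [default_link_schedule()]).
#' @param sweep Gap-fill k sweep (default [default_k_sweep()]).
#' @param limits [path_limits()] for the path search.
#' @param circ_k,circ_end_len,circ_max_fragment Circularization parameters
#'   (defaults 80, 200, 3500).
#' @param compare_blunt Also assemble the full read set and compare blunt-end
#'   fractions (slower; default `FALSE`).
#' @param output_dir Directory for FASTA/TSV/JSON artifacts, or `NULL` to
#'   keep everything in memory.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(),
                       fastq1 = NULL, fastq2 = NULL,
                       reference = NULL,
                       bin_fractions = c(0.35, 0.10, 0.03),
                       bin_thresholds = NULL,
                       trim_q = 15,
                       assembly_k = 48, assembly_min_count = 2,
                       assembly_min_len = 500,
                       scaffold_k = 26, scaffold_min_support = 5,
                       schedule = default_link_schedule(),
                       sweep = default_k_sweep(),
                       limits = path_limits(),
                       circ_k = 80, circ_end_len = 200,
                       circ_max_fragment = 3500,
                       compare_blunt = FALSE,
                       output_dir = NULL) {
  check_scalar_number(seed, "seed")
  if (!is.null(sim)) {
    if (!inherits(sim, "sim_config")) stopf("invalid configuration: field 'sim' must be a sim_config")
    sim$seed <- seed
  } else {
    for (f in c("fastq1", "fastq2")) {
      p <- get(f)
      if (is.null(p) || !file.exists(p)) {
        stopf("invalid configuration: field '%s' must name an existing FASTQ when sim is NULL", f)
      }
    }
    if (is.null(reference)) {
      stopf("invalid configuration: field 'reference' is required for external reads")
    }
  }
  if (!is.null(bin_thresholds)) {
    if (length(bin_thresholds) && any(diff(bin_thresholds) <= 0)) {
      stopf("invalid configuration: field 'bin_thresholds' must be strictly increasing")
    }
  } else if (length(bin_fractions) && any(diff(bin_fractions) >= 0)) {
    stopf("invalid configuration: field 'bin_fractions' must be strictly decreasing")
  }
  if (any(diff(sweep) >= 0)) {
    stopf("invalid configuration: field 'sweep' must be strictly decreasing")
  }
  if (!inherits(limits, "path_limits")) {
    stopf("invalid configuration: field 'limits' must be a path_limits object")
  }
  structure(list(
    seed = seed, sim = sim, fastq1 = fastq1, fastq2 = fastq2,
    reference = reference, bin_fractions = bin_fractions,
    bin_thresholds = bin_thresholds, trim_q = trim_q,
    assembly_k = assembly_k, assembly_min_count = assembly_min_count,
    assembly_min_len = assembly_min_len, scaffold_k = scaffold_k,
    scaffold_min_support = scaffold_min_support, schedule = schedule,
    sweep = sweep, limits = limits, circ_k = circ_k,
    circ_end_len = circ_end_len, circ_max_fragment = circ_max_fragment,
    compare_blunt = compare_blunt, output_dir = output_dir
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected (with the offending name); missing keys take
#' their defaults. The nested `sim` block maps to [sim_config()] and
#' `limits` to [path_limits()].
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stopf("unknown configuration key '%s'", unknown[1])
  }
  if (!is.null(raw$sim)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(raw$sim), sim_known)
    if (length(sim_unknown)) stopf("unknown configuration key 'sim.%s'", sim_unknown[1])
    raw$sim <- do.call(sim_config, raw$sim)
  }
  if (!is.null(raw$limits)) raw$limits <- do.call(path_limits, raw$limits)
  do.call(run_config, raw)
}

#' Save a run configuration as YAML
#'
#' Round-trips with [load_run_config()].
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- if (!is.null(x$sim)) unclass(x$sim)
  x$limits <- unclass(x$limits)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full assembly workflow
#'
#' Executes, in order: simulate (or load) linked reads; count index
#' multiplicity and extract bins; quality-trim and assemble the most
#' selective bin into unitigs; iteratively scaffold the contigs against the
#' related reference; fill gaps over successive bins with per-gap reference
#' enrichment; join the scaffold ends into a circle; canonically rotate and
#' evaluate. All randomness flows from the single configuration seed, so a
#' repeated run is byte-identical.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with the final `genome`, `circular` flag,
#'   per-stage log tibble (`stages`), the intermediate tables (index counts,
#'   contigs, scaffolds, gap-fill results) and the evaluation reports.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config object")
  t0 <- Sys.time()
  stages <- list()
  log_stage <- function(stage, detail) {
    stages[[length(stages) + 1L]] <<- tibble(stage = stage, detail = detail)
  }

  # --- input ------------------------------------------------------------
  truth <- NULL
  refs <- NULL
  if (!is.null(config$sim)) {
    refs <- generate_genomes(config$sim)
    simres <- simulate_linked_reads(refs, config$sim)
    reads <- simres$reads
    truth <- simres$truth
    log_stage("simulate", sprintf("%d pairs from %d bp organelle + %d bp nuclear",
                                  nrow(reads), config$sim$organelle_length,
                                  config$sim$nuclear_length))
  } else {
    reads <- read_linked_fastq(config$fastq1, config$fastq2)
    log_stage("load", sprintf("%d pairs from %s", nrow(reads), config$fastq1))
  }
  reference <- config$reference
  if (!is.null(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- unname(read_fasta(reference)[1])
  }
  if (is.null(reference)) {
    reference <- mutate_reference(refs$organelle, config$sim$related_divergence,
                                  seed = derive_seed(config$seed, 7))
    log_stage("reference", sprintf("surrogate related reference at %.1f%% divergence",
                                   100 * config$sim$related_divergence))
  }

  # --- binning ----------------------------------------------------------
  counts <- count_index_multiplicity(reads)
  thresholds <- config$bin_thresholds
  if (is.null(thresholds)) {
    thresholds <- vapply(config$bin_fractions, function(f) {
      threshold_for_top_fraction(counts, f)
    }, 0L)
    thresholds <- sort(unique(thresholds))
  }
  bins <- lapply(thresholds, function(t) bin_reads(reads, counts, t))
  degenerate <- length(bins) == 0
  log_stage("bin", if (degenerate) {
    "no bin thresholds: assembling the full read set (degenerate mode)"
  } else {
    paste0("thresholds ", paste(thresholds, collapse = "/"), " capture ",
           paste(sprintf("%.1f%%", 100 * vapply(bins, attr, 0, "fraction_of_total")),
                 collapse = "/"), " of pairs")
  })

  # --- assembly of the top bin -----------------------------------------
  top_bin <- if (degenerate) reads else bins[[length(bins)]]
  trimmed <- trim_reads(top_bin, q = config$trim_q,
                        min_len = config$assembly_k)
  graph <- withCallingHandlers(
    build_kmer_graph(trimmed, k = config$assembly_k,
                     min_count = config$assembly_min_count),
    plastidlinker_even_k = function(w) invokeRestart("muffleWarning")
  )
  contigs <- build_unitigs(graph, min_len = config$assembly_min_len)
  if (nrow(contigs) == 0) {
    stopf(paste0("assembly produced no contig of at least %d bp; ",
                 "the selected bin is too shallow or too deep/noisy ",
                 "(adjust bin_fractions/bin_thresholds or assembly_min_len)"),
          config$assembly_min_len)
  }
  log_stage("assemble", sprintf("%d contigs >= %d bp from %d trimmed pairs (k = %d)",
                                nrow(contigs), config$assembly_min_len,
                                nrow(trimmed), config$assembly_k))
  blunt <- list(top_bin = blunt_end_fraction(graph), all_reads = NA_real_)
  if (isTRUE(config$compare_blunt)) {
    all_graph <- withCallingHandlers(
      build_kmer_graph(trim_reads(reads, q = config$trim_q,
                                  min_len = config$assembly_k),
                       k = config$assembly_k,
                       min_count = config$assembly_min_count),
      plastidlinker_even_k = function(w) invokeRestart("muffleWarning")
    )
    blunt$all_reads <- blunt_end_fraction(all_graph)
    log_stage("blunt", sprintf("blunt ends: %.1f%% (top bin) vs %.1f%% (all reads)",
                               100 * blunt$top_bin, 100 * blunt$all_reads))
  }

  # --- scaffolding ------------------------------------------------------
  scaffolds <- iterate_distances(contigs, reference,
                                 schedule = config$schedule,
                                 k = config$scaffold_k,
                                 min_support = config$scaffold_min_support)
  target_id <- pick_target_scaffold(scaffolds, reference, k = config$scaffold_k)
  target <- scaffolds$sequence[scaffolds$id == target_id]
  log_stage("scaffold", sprintf("%d scaffolds; on-target %s: %d bp with %d gaps",
                                nrow(scaffolds), target_id, nchar(target),
                                nrow(find_gaps(target))))

  # --- gap filling ------------------------------------------------------
  nb <- length(bins)
  fill_bins <- c(
    if (nb >= 2) list(bins[[nb - 1]]) else if (nb == 1) list(bins[[1]]),
    if (nb >= 3) list(bins[[nb - 2]]),
    list(reads)
  )
  filled <- fill_all_gaps(target, fill_bins, reference = reference,
                          sweep = config$sweep, limits = config$limits)
  n_open <- nrow(find_gaps(filled$scaffold))
  log_stage("fill", sprintf("%d of %d gap-fill attempts closed; %d gap(s) remain",
                            sum(filled$results$status == "closed"),
                            nrow(filled$results), n_open))

  # --- circularization --------------------------------------------------
  circ_reads <- if (nb >= 2) bins[[nb - 1]] else reads
  genome <- filled$scaffold
  circular <- FALSE
  if (n_open == 0) {
    joined <- join_ends(genome, circ_reads, k = config$circ_k,
                        max_fragment = config$circ_max_fragment,
                        end_len = config$circ_end_len,
                        limits = config$limits)
    genome <- joined$sequence
    circular <- joined$circular
    log_stage("circularize", joined$status)
    if (circular) genome <- canonical_rotation(genome, reference = reference)
  } else {
    log_stage("circularize", "skipped: gaps remain")
  }

  # --- evaluation -------------------------------------------------------
  comp <- composition(genome)
  ambig <- ambiguity_stats(genome)
  ir <- tryCatch(detect_inverted_repeat(genome), error = function(e) NULL)
  coverage <- read_coverage(reference, top_bin)
  truth_cmp <- NULL
  if (!is.null(refs)) {
    truth_cmp <- compare_to_truth(genome, refs$organelle, circular = circular)
    log_stage("evaluate", sprintf("vs truth: exact = %s, length diff = %d, mismatches = %s",
                                  truth_cmp$exact, truth_cmp$length_diff,
                                  format(truth_cmp$n_mismatch)))
  } else {
    log_stage("evaluate", sprintf("final genome %d bp, GC %.1f%%", nchar(genome), comp$gc))
  }

  report <- structure(list(
    genome = genome, circular = circular,
    stages = bind_rows(stages),
    seed = config$seed, config = config,
    index_counts = counts, thresholds = thresholds, degenerate_bins = degenerate,
    contigs = contigs, scaffolds = scaffolds, target_scaffold = target_id,
    blunt = blunt, fill_results = filled$results, gaps_remaining = n_open,
    composition = comp, ambiguity = ambig, ir = ir, coverage = coverage,
    truth_comparison = truth_cmp, truth_refs = refs,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")

  if (!is.null(config$output_dir)) write_run_artifacts(report, config$output_dir)
  report
}

write_run_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(setNames(report$genome, "assembly"), file.path(dir, "assembly.fasta"))
  write_fasta(setNames(report$contigs$sequence, report$contigs$id),
              file.path(dir, "contigs.fasta"))
  write_fasta(setNames(report$scaffolds$sequence, report$scaffolds$id),
              file.path(dir, "scaffolds.fasta"))
  readr::write_tsv(tibble(index = report$index_counts$index,
                          n_pairs = report$index_counts$n_pairs),
                   file.path(dir, "index_counts.tsv"))
  readr::write_tsv(report$fill_results, file.path(dir, "gap_fill.tsv"))
  cfg <- unclass(report$config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  cfg$limits <- unclass(cfg$limits)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d bp %s genome (seed %s, %.1f s)\n",
              nchar(x$genome), if (x$circular) "circular" else "linear",
              format(x$seed), x$elapsed))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-12s %s\n", x$stages$stage[i], x$stages$detail[i]))
  }
  invisible(x)
}
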