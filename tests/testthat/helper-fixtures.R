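# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small but complete linked-read library: 8 kb organelle with a planted
# 300 bp / 3-mismatch IR, 100 kb nuclear background, 30k pairs
small_sim_config <- function(seed = 3) {
  sim_config(seed = seed, organelle_length = 8000, nuclear_length = 100000,
             ir_length = 300, total_pairs = 30000, barcode_pool = 800,
             frag_len_median = 8000)
}

small_sim <- function() {
  cached("small_sim", function() {
    cfg <- small_sim_config()
    refs <- generate_genomes(cfg)
    sim <- simulate_linked_reads(refs, cfg)
    list(config = cfg, refs = refs, reads = sim$reads, truth = sim$truth,
         counts = count_index_multiplicity(sim$reads))
  })
}

# full study-scale simulation: 30 kb organelle at 200:1 copy weight, 1 Mb
# nuclear background, 200k pairs (the default generator conditions)
default_sim <- function() {
  cached("default_sim", function() {
    cfg <- sim_config(seed = 1)
    refs <- generate_genomes(cfg)
    sim <- simulate_linked_reads(refs, cfg)
    list(config = cfg, refs = refs, reads = sim$reads, truth = sim$truth)
  })
}
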