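# plastidlinker

Assembly of small high-copy organelle genomes — chloroplast genomes in
particular — from barcoded linked-read libraries, in R.

## The problem

A total-DNA library from a plant samples the chloroplast genome hundreds of
times more deeply than the nuclear genome, because each cell carries hundreds
of plastome copies. Linked-read library preparation partitions long DNA
fragments into droplets and tags every read pair from a droplet with the same
14 bp index. Ranking indices by the number of read pairs associated with them
("index multiplicity") therefore yields bins that are both **enriched for
plastid template** and **co-localized on long fragments**: assembling only a
high-multiplicity bin gives a dramatically simpler de Bruijn graph than
assembling everything. `plastidlinker` implements that whole workflow for
people who want to pull a finished, circular organelle genome out of a
linked-read library without purifying organelles at the bench:

1. **Bin** — count pairs per fully sequenced index (`count_index_multiplicity()`),
   extract multiplicity bins (`bin_reads()`, thresholds `>= t`, nested).
2. **Assemble** — quality-trim (`trim_reads()`, running-sum argmax rule),
   count canonical k-mers (`build_kmer_graph()`, k = 48, singletons removed),
   emit unitigs (`build_unitigs()`; maximal non-branching paths, no bubble
   popping). Graph complexity is measured by the *blunt-end fraction*
   (`blunt_end_fraction()`): the share of k-mer vertices with no neighbour in
   at least one direction.
3. **Scaffold** — order and orient contigs against a related-species plastome
   using paired k-mers (k = 26) at separations swept from 250 bp to 16 kb
   (`iterate_distances()`); each pair whose two k-mers land uniquely in
   different contigs votes for a junction with gap estimate
   `d − (left k-mer → contig 3' end) − (contig 5' end → right k-mer)`.
4. **Finish** — close each `N` gap by bounded depth-first path search through
   a Bloom filter of read k-mers, sweeping k from 125 down to 35
   (`fill_all_gaps()`), with per-gap read enrichment against the reference
   (`enrich_reads_for_gap()`); search limits: B = 3000 branch events,
   P = 20 paths, F = 5000 bp flank search.
5. **Circularize** — join the scaffold ends through read-supported sequence
   (`join_ends()`, k = 80, ends treated as a long-insert "read pair"), rotate
   canonically, and evaluate: composition, ambiguity accounting, exact-seed
   read coverage, and detection of the two-copy inverted repeat
   (`detect_inverted_repeat()`).

A seeded linked-read simulator (`sim_config()`, `generate_genomes()`,
`simulate_linked_reads()`) generates a circular organelle with a planted
inverted repeat, a nuclear background, barcoded droplets with overdispersed
per-index counts, and per-pair ground truth, so every stage is testable
without any external data.

## Worked example

```r
library(plastidlinker)

cfg <- run_config(
  seed = 3,
  sim = sim_config(organelle_length = 8000, nuclear_length = 100000,
                   ir_length = 300, total_pairs = 30000, barcode_pool = 800,
                   frag_len_median = 8000),
  schedule = c(seq(250, 2000, 250), seq(2500, 7000, 500))
)
report <- run_all(cfg)
report
```

```
<run_report> 8000 bp circular genome (seed 3, 5.5 s)
  simulate     30000 pairs from 8000 bp organelle + 100000 bp nuclear
  reference    surrogate related reference at 1.0% divergence
  bin          thresholds 90/152/190 capture 35.1%/10.2%/3.4% of pairs
  assemble     3 contigs >= 500 bp from 1022 trimmed pairs (k = 48)
  scaffold     1 scaffolds; on-target scaffold001: 7512 bp with 2 gaps
  fill         2 of 2 gap-fill attempts closed; 0 gap(s) remain
  circularize  circular
  evaluate     vs truth: exact = TRUE, length diff = 0, mismatches = 0
```

Reading the log: 30,000 simulated pairs were binned at derived thresholds
(90/152/190 pairs per index, capturing 35.1%/10.2%/3.4% of pairs); the most
selective bin assembled into 3 contigs; scaffolding against a 1%-diverged
related reference produced a single on-target 7,512 bp scaffold with 2 gaps;
both gaps closed; the ends joined into an 8,000 bp circle that matches the
simulated truth exactly. `glance(report)` returns the same numbers as a
one-row tibble (final length, GC, IR length and substitutions, gap counts,
exact-match flag), and `tidy(report)` the stage log.

At the full study scale (`run_config(seed = 1)`: 30 kb organelle at 200:1
copy weight, 1 Mb nuclear background, 200k pairs) the run takes ~20 s and
recovers the circular genome with the planted 440 bp inverted repeat;
variant sites deep inside the repeat can be phase-ambiguous by construction
— see the methods vignette (`vignettes/plastid-assembly.Rmd`) for the model,
parameter rationale and known limitations.

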