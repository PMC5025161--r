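---
title: "Assembling high-copy plastid genomes from linked reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling high-copy plastid genomes from linked reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidlinker)
```

## The problem and the idea

A total-DNA sequencing library from a plant contains the nuclear genome at
one copy per cell and the chloroplast genome at hundreds of copies, so
plastid loci are massively oversampled. Linked-read library preparation adds
a second handle: long DNA fragments are partitioned into droplets, and every
short-read pair derived from one droplet carries the same 14 bp index. Read
pairs can therefore be grouped by index, and the number of pairs associated
with an index reflects how much template its droplet held.

`plastidlinker` exploits both properties. Indices are ranked by read-pair
multiplicity; the top bins are strongly enriched for plastid template and,
crucially, hold reads that are *co-localized* on long fragments. Assembling
only a high-multiplicity bin yields a far simpler de Bruijn graph than the
full read set — the package quantifies this with the blunt-end fraction, the
share of k-mer vertices lacking a neighbour in at least one direction. The
workflow is:

1. **Bin** read pairs by index multiplicity (`count_index_multiplicity()`,
   `bin_reads()`).
2. **Assemble** the most selective bin into unitigs over a canonical k-mer
   graph (`build_kmer_graph()`, `build_unitigs()`).
3. **Scaffold** contigs against a related-species plastome using paired
   k-mers at a swept distance schedule (`iterate_distances()`).
4. **Fill gaps** by bounded depth-first path search through a Bloom-filter
   de Bruijn graph, over a descending k sweep, with per-gap read enrichment
   against the reference (`fill_all_gaps()`, `enrich_reads_for_gap()`).
5. **Circularize** by joining the scaffold ends through read-supported
   sequence (`join_ends()`), then rotate canonically and evaluate
   (`composition()`, `ambiguity_stats()`, `detect_inverted_repeat()`,
   `read_coverage()`, `compare_to_truth()`).

`run_all()` drives all stages from one seeded configuration.

## The synthetic linked-read model

Because every stage is graph- and coverage-sensitive, the package ships a
generator (`sim_config()`, `generate_genomes()`, `simulate_linked_reads()`)
that reproduces the statistical structure the method exploits, with per-pair
ground truth. Its default conditions: a 30 kb circular organelle carrying a
two-copy 440 bp inverted repeat whose copies differ at exactly 3 positions,
a 1 Mb nuclear background, a 200:1 organelle:nuclear copy ratio, 5,000
barcodes, and 200,000 pairs of 2x125 bp reads with 0.2% substitution error.

Design choices worth knowing:

* **Fragment model.** Fragment sources are drawn proportional to
  copy-ratio-weighted genome length. Nuclear fragments are sheared
  high-molecular-weight DNA: lognormal lengths (median 20 kb) truncated to
  1–100 kb. An organelle "fragment" is modelled as a multi-copy plastome
  particle — a droplet that captures a chloroplast receives several circular
  genome equivalents of template (`plastome_copies_per_gem`, default mean 4),
  since plastid genomes come packaged as multi-copy nucleoids. Per-fragment
  read yield is gamma-Poisson with mean proportional to template length
  (inserts sample the partitioned template per base). Together these make
  per-index counts overdispersed *and* make high-multiplicity indices
  systematically organelle-enriched. With source-blind yields the enrichment
  would be a coin flip, which contradicts the premise the binning step rests
  on; the particle model is the mechanism that produces it.
* **Circularity.** Organelle read coordinates wrap the origin; the truth
  table records wrapped 0-based starts.
* **Qualities.** Constant Q37 with a linear decay to Q12 over the final 15
  cycles, so the `q = 15` trimming rule actually removes bases.
* **Not modelled.** PCR duplicates, chimeric fragments, indel errors, and
  barcode errors beyond an occasional `N` in the emitted index. Passing
  tests therefore say nothing about robustness to indel-rich platforms or
  heavy barcode corruption.

The related-species guide is derived with `mutate_reference()` at 1%
substitution divergence, matching the identity typically seen between
congeneric plastomes.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| assembly k | 48 bp | long enough to be unique in a 30–130 kb plastome, short enough for 125 bp reads |
| assembly `min_count` | 2 | removes singleton error k-mers; deliberate substitute for coverage-model filtering |
| contig `min_len` | 500 bp | scaffolding uses contigs of at least 500 bp |
| scaffold pair k | 26 bp | tolerant of ~1% reference divergence (0.99^26 ≈ 0.77 of pairs survive) |
| distance schedule | 250–16,000 bp | step 250 to 2 kb, 500 to 9 kb, 1000 to 16 kb; output of each pass feeds the next |
| link `min_support` | 5 votes | drops incidental one-off k-mer coincidences |
| fill sweep | k = 125..95 by 5, 94..35 by 1 | high k first for specificity, descending for sensitivity |
| search limits | B = 3000, P = 20, F = 5000 | branch events, paths collected, flank search length |
| Bloom target FPR | 0.001 | ~1 spurious branch per 300 extensions at 3 alternatives per step |
| classification `min_share` | 0.15 | a 125 bp read at 1% divergence + 0.2% error keeps ≥ 15% of its 25-mers with high probability |
| circularization | k = 80, ends 200 bp, max fragment 3500 bp | junction k-mers must be unique; the missing inter-end span is bounded |
| bin fractions | 0.35 / 0.10 / 0.03 | see below |

**Bin selectivity at desk scale.** On the simulated 200k-pair library the
default ladder keeps the top bin at roughly 50x organelle depth, which k = 48
counting with `min_count = 2` needs to avoid spurious contig breaks. On a
production-scale library the same role is played by absolute thresholds
(pass `bin_thresholds`); selectivity should always be chosen so the top bin
retains near-complete coverage of the target — `read_coverage()` against the
related reference is the check.

## Numerical and algorithmic choices

* **Canonical k-mers.** All counting, Bloom membership and adjacency are on
  the lexicographic minimum of a k-mer and its reverse complement. Odd k
  avoids palindromic k-mers; even k is accepted with a warning and
  palindromes then break unitig chains deterministically.
* **Unitigs.** Maximal non-branching paths; no tip or bubble removal.
  Graph simplification is deliberately absent — in this method the binning
  is what simplifies the graph. Branch-free circular components are opened
  at their minimal canonical k-mer; output contigs are canonically oriented
  and sorted, so assembly output is byte-deterministic.
* **Link arithmetic.** A reference k-mer pair at separation `d` whose
  members land in different contigs (unique canonical occurrence only) votes
  for a junction with gap estimate `d − (left k-mer → contig 3' end) −
  (contig 5' end → right k-mer)`. Greedy layout accepts links by support,
  then smaller |gap|, then lexicographic ids; each contig end takes one
  partner; a link that would close a cycle is skipped, which breaks a
  circular chromosome's contig cycle at its weakest junction — the two ends
  are rejoined later by `join_ends()`. Zero or negative gap estimates render
  a single `N`; the path search resolves the true junction, collapsing any
  real overlap.
* **Goal test in the path search.** Membership lookups are canonical, but
  the goal is matched literally (same orientation as the walk). A
  strand-insensitive goal test lets a walk that runs into an inverted repeat
  come back reflected and terminate on the goal's reverse complement,
  producing spurious unequal-length paths and even pre-empting the true
  path. A fill is only splice-consistent if it ends with the goal k-mer as
  spelled in the scaffold.
* **Multi-path resolution.** One path wins outright. Two to P equal-length
  paths with ≥ 95% pairwise identity are resolved by column-majority
  consensus, ties taking the first-found path's base (children explored in
  A<C<G<T order, so the rule is deterministic); anything else is
  `ambiguous`. Once a k returns `ambiguous` the sweep stops for that gap:
  lowering k only ever adds paths.
* **Fill splicing.** The accepted path replaces the scaffold span from start
  k-mer through goal k-mer; flanking bases outside that span are untouched
  (and the k-mer spans themselves are byte-identical by construction). A
  path shorter than 2k means the flanking contigs genuinely overlap and the
  overlap collapses.
* **Seeds.** One master seed fans out to per-stage seeds by a fixed Lehmer
  step, so `run_all()` is byte-reproducible and stages can be reproduced in
  isolation.

## Known limitations

* **Repeat-internal variant phasing.** Inside a two-copy inverted repeat,
  single-k-mer evidence cannot tell the copies apart farther than k−1 bases
  from a repeat boundary: at a between-copy variant site both bases sit in
  the Bloom filter with equal support, the candidate paths are equal-length
  and near-identical, and the consensus tie-break — not data — picks the
  base. Paired-end or linked-barcode constraints would resolve this, but
  both are deliberately outside the path engine (droplet fragments are far
  longer than the IR separation, so barcodes carry no signal here either).
  Practically: IR-internal variant sites are reliable only when the fill
  k-mers reach them from unique flanking sequence; with the default 440 bp
  IR and fill k up to ~100, sites in the central ~240 bp are at risk when a
  gap falls on an IR copy. The planted-IR recovery test passes when the
  contigs carry the IR through intact (the usual case, since unitig chains
  traverse an IR whose interior is locally consistent) and fails loudly when
  phasing was decided by tie-break.
* **Coverage placement is exact-seed, ungapped** (`read_coverage()`): a
  deliberate simplification adequate for presence/absence coverage at ≤ 1%
  divergence, not a read aligner.
* **IR detection merges substitution-separated anchors on one
  anti-diagonal**; indel-bearing IR copies are out of scope, and copy edges
  closer than the 24 bp anchor length to a variant site are trimmed from
  the reported repeat.
* **The simulator's problem sizes** (30 kb organelle, 1 Mb background, 200k
  pairs; 8 kb / 100 kb / 30k pairs in the test fixtures) were chosen so the
  full workflow and its tests represent the method faithfully at desk scale;
  absolute performance numbers from these runs do not transfer to
  production-scale libraries, though the pipeline's structure is unchanged.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- run_config(
  seed = 3,
  sim = sim_config(organelle_length = 8000, nuclear_length = 100000,
                   ir_length = 300, total_pairs = 30000, barcode_pool = 800,
                   frag_len_median = 8000),
  schedule = c(seq(250, 2000, 250), seq(2500, 7000, 500))
)
report <- run_all(cfg)
report
glance(report)
```

The report's stage log shows pairs simulated, bin thresholds and captured
fractions, contigs assembled, the on-target scaffold and its gap count,
gap-fill outcomes per round, the circularization status, and — for simulated
runs — exact agreement with the planted truth.
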