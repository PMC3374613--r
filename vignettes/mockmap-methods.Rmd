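---
title: "Benchmarking read mapping for metagenomic community profiling with mockmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking read mapping for metagenomic community profiling with mockmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockmap)
```

## The problem

Shotgun metagenomic profiling asks: given millions of short reads from a
microbial community, which organisms are present and at what abundance?
The standard answer maps reads against a collection of reference genomes
and summarizes coverage per genome. Every step of that pipeline involves
choices — how to dereplicate near-identical reference strains, how strictly
to filter alignments, what to do with reads that map equally well to
several genomes, and what coverage justifies calling a taxon "present" —
and each choice trades sensitivity against taxonomic resolution.

mockmap packages that whole pipeline together with a simulator of mock
communities of *known* composition, so every choice can be quantified
against ground truth: each simulated read carries a label saying which
strain, sequence, position and strand it came from, and the evaluation
module scores every read's fate against that label.

## Pipeline overview

1. **refdb** — build a strain-indexed reference database. Every sequence ID
   carries a prefix unique to its strain so alignments to any contig or
   plasmid roll back up to the parent genome. Near-redundant strains are
   removed per species (`dereplicate()`), keeping the longer genome.
2. **mocksim** — simulate a community: paired-end 100 bp reads with uniform
   insert length in a configurable range (default 180–250 bp,
   forward/reverse orientation), i.i.d. substitution errors, and a truth
   table.
3. **screen** — DUST-style low-complexity masking; reads mostly masked are
   removed, and the surviving mate of a broken pair is *orphaned* into a
   fragment set that is mapped single-ended alongside the pairs.
4. **align** — a seed-and-extend mapper enforcing the two filters of the
   reference pipeline: minimum aligned length fraction of the query (`-l`)
   and minimum identity within the alignment (`-s`). All equally-best
   placements are retained per read. External SAM can be ingested instead.
5. **resolve** — convert tied best hits into placements under `top_random`,
   `unique_only`, `topN` or `all_hits` rules.
6. **profile** — per-strain breadth (% bases covered at least once) and
   depth (mean per-base coverage), a joint detection cutoff (default 1%
   breadth and 0.01x depth, both inclusive), and species/genus rollups.
7. **evaluate** — read-fate classification against truth, Spearman
   correlation of depth with the specified concentrations, chi-square
   comparison of depth profiles, and paired log-depth tables for
   reference-vs-amended database experiments.

## Models and key parameters

### Genome similarity and dereplication

Redundancy screening needs a scalar genome-wide similarity. mockmap uses
**canonical k-mer containment**: the fraction of the smaller genome's
distinct canonical k-mers (default k = 21) shared with the other genome.
It is deterministic, fast, monotone in true sequence identity, and scores a
subset genome near 1 — exactly the genomes that contribute no unique
sequence. `genome_similarity()` returns this raw containment.

Containment and nucleotide identity live on different scales: two genomes
with per-base divergence $d$ share roughly $(1-d)^k$ of their k-mers.
`dereplicate()` therefore converts containment $c$ to the Mash-style
identity estimate $c^{1/k}$ before comparing against the threshold, so the
default `threshold = 0.90` means "90% genome-wide identity" (a 2%-divergent
strain scores ≈ 0.98 and is removed; the relaxed 0.83 setting mirrors
screening of large, heterogeneous strain groups). Dereplication is greedy
per species in chromosome-length-descending order (prefix as tie-break), so
the longest genome of a species always survives and the procedure is
deterministic and idempotent. Protected strains are never removed but do
serve as kept representatives; plasmids are excluded from the similarity
computation and retained with their kept strains.

### The read simulator

Abundance is modeled as **DNA-mass proportional**: a fragment comes from
strain $i$ with probability proportional to `concentration[i] * total
genome length[i]`, because shotgun sequencing samples base pairs, not
cells. Rank-based comparisons against the concentration vector are
unaffected by any monotone weighting. Fragment start positions are uniform
over valid positions; insert length is uniform over `insert_range`; each
fragment's strand is random; mates read inward from the two fragment ends
(forward/reverse). Substitution errors are i.i.d. per base and never
reproduce the original base. Qualities are constant Phred 40 ('I') because
nothing downstream consumes them. Identical seeds give byte-identical
FASTQ and truth files.

What the simulator does **not** emulate: indel sequencing errors,
quality-profile or GC bias, platform-specific artifacts, real inter-genome
homology structure (synthetic genomes are i.i.d. random, so distinct
strains share essentially no k-mers). Consequently a passing test shows the
pipeline's bookkeeping and decision rules are right under clean conditions;
it does not show robustness to real cross-mapping between genuinely
homologous genomes. Real homology is emulated *explicitly* where it is the
object of study — identical duplicate genomes, or congeners built by
`mutate_genome()` at a chosen divergence.

### The mapper

Candidate loci come from a canonical k-mer seed index (default k = 16;
seeds occurring at more than `max_seed_occupancy = 1024` positions are
dropped as repetitive, which makes seed-free repeats such as poly-A tracts
unmappable — intended, since such reads should have been screened out).
Seed hits are clustered by diagonal, and each cluster is extended by
**banded affine-gap local alignment** (band half-width
`ceil(read_length * (1 - min_similarity)) + 2`, so no alignment that could
pass the identity filter is clipped by the band). Scoring is match +1,
mismatch −2, gap of length $L$ costs $3 + L$. A full-length exact match is
recognized without dynamic programming (it is provably optimal).

Each locus contributes its single best local alignment. Soft-clipping is
free during extension and is then *judged by the length filter*:
`query_aligned_fraction` is the unclipped fraction of the read, so
`min_length_fraction = 1` admits only reads whose optimal alignment is
end-to-end. This mirrors how a production aligner behaves — a read whose
best alignment clips two mismatching trailing bases *fails* a 100% length
requirement even though a slightly worse end-to-end alignment exists. That
is precisely why the strictest length setting maps strictly fewer reads
than the 75% setting in the filter-grid experiment, while identity
constraints matter mainly when the community strain is absent and only a
divergent congener is available.

Identity is matches over all alignment columns, gap columns included. Ties
are exact integer score equality; duplicate loci (same sequence, start,
strand) are collapsed; no secondary tie-break is applied inside a hit set —
resolution policy belongs to the resolve module.

**Pairing.** Mates are mapped independently; among tied hits, combinations
forming a proper pair — opposite strands, forward mate leftmost, fragment
span (leftmost start to rightmost end) within `insert_range` — are
promoted and non-participating ties demoted. The fragment-span reading of
the insert constraint matches the simulator's truth definition of insert
length; with 100 bp reads an inner-gap reading would make the conventional
180–250 setting unsatisfiable.

### Resolution strategies

`top_random` picks uniformly among ties with a generator keyed on
`(seed, read_id)` — a hash, not a stream RNG — so resolution is independent
of read order and parallel chunking; the same seed gives byte-identical
SAM no matter how the input was shuffled. `unique_only` places a read only
when it has exactly one best hit. `topN` emits all ties when there are at
most `n` (default 5) and otherwise suppresses the read entirely.
`all_hits` emits everything. With multi-placement strategies, downstream
coverage counts every emitted placement, and fate classification takes the
read's best fate while reporting how many reads were ambiguous.

### Coverage, detection and rollup

Breadth is the percentage of a strain's bases (chromosome plus plasmids)
covered at least once; depth is summed per-base coverage divided by total
strain length. Both are accumulated from aligned reference spans
`[ref_start, ref_end)`, so deletions inside an alignment count as covered
span and soft-clipped read bases do not contribute. Detection requires
breadth ≥ 1% **and** depth ≥ 0.01x, both inclusive at the boundary (the
cutoff is stated without boundary semantics in the field; inclusivity is
this package's documented convention). Species/genus rollups are
*unweighted means* over member strains — the convention used when plotting
genus-level depth — with a taxon counted as detected when any member
strain is; relative abundance normalizes depth over detected taxa, and a
profile with no detected taxa yields an empty table.

### Evaluation

`classify_fates()` gives each read exactly one fate (`correct_strain`,
`correct_at_level`, `wrong_taxon`, `unmapped`, `suppressed_multi`); counts
always sum to the read total. `spearman_rank()` is the tie-corrected
(average-rank) coefficient and refuses constant vectors rather than
returning a number. `chisq_depth_compare()` scales profile `b` to the
total of `a` (`e_i = b_i * sum(a) / sum(b)`), computes
$X^2 = \sum (a_i - e_i)^2 / e_i$ on $n-1$ degrees of freedom, and reads
p ≥ 0.05 as "similar"; depths are not counts, so this is a pragmatic
concordance measure, not an inferential test — callers must drop
undetected strains first (zero expected cells are an error, not a fudge).
`depth_log_ratio()` reports paired log10 depths with zeros as missing
rather than −∞.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; SAM output is 1-based.
- Filter comparisons use a 1e−9 tolerance below the threshold so that an
  identity of exactly 0.80 passes `-s 0.80` despite floating-point
  representation.
- DUST windows score $\sum_t c_t(c_t-1)/2 \,/\, (L-1)$ over the $L$
  N-free trinucleotides of the window (window 64, level 2.0 — the classic
  parameterization); a window scoring above the level is masked in full,
  flagged spans are merged, and N runs are always masked. Windows with
  fewer than two countable triplets score 0.
- A read is removed when its masked fraction strictly exceeds
  `max_masked_fraction` (default 0.5 — the reference pipeline states only
  that masked sequence was removed, so the fraction is configurable).
  Reads consisting entirely of N are removed unconditionally: they are
  unalignable, and this keeps the limiting threshold of 1 meaningful
  (nothing else is removed there).
- Tied DP cells prefer the shorter alignment (stop > diagonal > reference
  gap > query gap in strict order), making extension deterministic.
- Empty databases, empty read sets, empty hit sets and zero-coverage
  strains are all representable and tested; strains with no placements get
  explicit zero rows rather than being dropped.

## Problem sizes

Test and acceptance runs use synthetic genomes of 20–100 kb and read sets
of 10³–10⁵ — sizes chosen so the full suite exercises every code path,
including a complete 3 × 2 filter grid over a 10-strain, 50,000-pair
community, in about a minute on one CPU. The data structures impose no
such limit: the index and coverage accumulators scale to real genome
collections linearly in total reference length.

## Known limitations

- The mapper is a benchmarking instrument, not a production aligner: no
  BAM/CRAM, no spliced or long-read modes, no base-quality-aware scoring,
  and no attempt to reproduce any specific external aligner's placements
  read-for-read (external SAM can be ingested for that).
- k-mer containment saturates for very high divergence (unrelated genomes
  share ~0 k-mers), so the identity estimate `c^(1/k)` is only meaningful
  near and above the dereplication thresholds it serves.
- The chi-square construction treats depths as if they were counts;
  p-values are comparative indices, not calibrated error rates.
- Multi-placement (topN/all-hits) coverage intentionally multi-counts
  reads; relative abundances under those strategies are not normalized for
  placement multiplicity.
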