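---
title: "Clustering-oriented short-read assembly: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-oriented short-read assembly: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustasm)
library(data.table)
```

## The model

Short-read de Bruijn assembly treats every length-k window of every read
as a unit. On instruments whose dominant error mode is base
substitution (at per-base rates around 0.5–2.5%), a single miscall
corrupts up to k consecutive windows, so at practical coverage most
*distinct* observed k-mers are erroneous, and the problem worsens as k
grows. `clustasm` addresses this before any graph exists, with an error
allowance parameter *p*: two k-mers are treated as observations of the
same genomic word when their Hamming distance, directly or through the
reverse complement, is at most *p*. A useful default intuition is
*p ≈ k ×* error rate — one allowed mismatch per 40-mer corresponds to a
2.5% per-base tolerance.

Clustering is exact, not heuristic: the Hamming graph over all distinct
canonical k-mers is built and its connected components are the
clusters. To avoid all-pairs comparison the package uses a pigeonhole
index: positions `[0, k)` are cut into *p* + 1 contiguous spans whose
lengths differ by at most one (longer spans first; see
`partition_spans()`). A pair within distance *p* has at most *p*
mismatching spans, so at least one span matches exactly; indexing the
i-th span of every k-mer (and of its reverse complement) in the i-th of
*p* + 1 hash tables therefore yields a candidate stream that provably
contains every true pair. Candidates are verified with an early-exit
Hamming comparison. Components are found by breadth-first search, with
member orientations propagated along the search forest from the
lexicographically smallest member.

Each cluster is summarised by its consensus: the occurrence-weighted
majority nucleotide per column, over members rotated onto a common
strand. Clusters can over-merge — most visibly where a repeat boundary
places two genuinely different words within 2*p* of each other through
an error bridge. The splitting rule undoes this: scanning columns left
to right (and nucleotides A<C<G<T within a column), the first minority
nucleotide *x* whose occurrence reaches `sp` times that of the
consensus nucleotide *y* pulls its members into a new node, and both
halves are re-examined recursively. Members are partitioned, never
duplicated, and the recursion terminates because each split strictly
reduces one side. For a cluster of q members the worst case is
O(q² × k), the quick-sort-like degenerate recursion; in practice
clusters are small and dominated by one high-count centre.

The consensus k-mers then become de Bruijn nodes. Edges are exact
(k−1)-overlaps in any orientation pair, located by hashing oriented
flanks; each edge's frequency is the number of consecutive-window read
observations that project onto it through the member map, which is the
only read-grounded notion of edge support that survives clustering.

## Graph cleaning, extension, scaffolding

Cleaning combines one spectral and three structural operations, all
monotone (node and link counts never increase) and deterministic:

* **Low-frequency trimming** removes links with support strictly below
  `cs`, then isolated nodes with coverage below `cs`.
* **Tip pruning** removes dead-end nodes no longer than `max_tip_len`
  whose junction offers an alternative link of at least equal
  frequency; candidates go lowest frequency first, ties by sequence,
  re-compacting between removals.
* **Bubble popping** merges pairs of parallel single-link-per-side
  branches no longer than `max_bubble_len` whose sequences align at
  identity at least `min_identity` (global alignment via Biostrings);
  the weaker branch's link frequencies and coverage are added to the
  survivor.
* **Chimeric-link removal** deletes links below `cs` that connect two
  busy junction sides and fall below half the median frequency of
  their neighbours.

After cleaning, free unitig ends are joined through exact overlaps
shorter than k: for L from k−1 down to the minimum overlap m, ends are
indexed by their length-L outward flanks and a join is made only when
the two ends are mutually unique partners. Ambiguous overlaps are never
joined, and self-joins are refused.

Scaffolding maps reads back onto the compacted graph by exact k-mer
seeding (first k-mer, falling back to the last) with base-level
verification at `min_map_identity` (default 0.95), following links
where a read crosses node ends; reads with more than one verified
placement are dropped as repeat-ambiguous. Junction-spanning read
chains resolve a node when its incident links pair up perfectly — every
chain entering by a link leaves by the same partner, each pairing seen
at least twice — in which case the node is duplicated per pairing
(Eulerian-style read threading) and the graph re-compacted. Anchored
mate pairs then vote for oriented contig links; a link needs `ss`
supporting pairs, its gap is the lower-median of per-pair inferred gaps
(library insert minus the distance each mate's outer end lies from its
contig edge), and conflicting links lose to the strongest claimant of
each contig side. Scaffold chains are laid out greedily by support,
shortest-insert library first; gaps are rendered as runs of `N` of
length `max(round(gap), 1)` — negative (overlapping) gaps are marked
with a single `N` rather than merged, since no overlap-verification
stage follows.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | — | k-mer length (bp); odd values avoid self-complementary k-mers |
| `p` | 0 | error allowance on k-mers (maximum Hamming distance); `p = 0` skips clustering |
| `sp` | 0.6 | splitting threshold; minority/consensus occurrence ratio that forces a node split |
| `cs` | 5 | spectral cutoff: minimum link frequency (and isolated-node coverage) |
| `ss` | 5 | minimum mate-pair support for a scaffold link |
| `m` | ⌊k/2⌋+1 | minimum exact overlap for sub-k extension |
| `ml` | 0 | minimum contig/scaffold length written to output (bp) |
| `max_tip_len` | 2k | maximum tip length (bp) |
| `max_bubble_len` / `min_identity` | 3k / 0.9 | bubble branch length and identity bounds |

`sp` is evaluated in exact integer arithmetic (the decimal is scaled to
a rational with denominator 10⁶) so thresholds like 0.6 behave
identically across platforms. Consensus ties resolve to the
alphabetically smallest nucleotide; the split scan order (columns left
to right, first qualifying column and nucleotide wins) is likewise a
fixed determinism rule. All sequence orderings use C-locale radix
sorts, making whole runs byte-reproducible.

## Design choices where the design was open

* **Occurrence weighting.** Consensus tallies and the split rule weight
  members by read occurrence count, not one-per-distinct-k-mer:
  occurrence is what distinguishes a 20-fold-covered genomic word from
  a count-1 satellite, and it is the quantity the spectral cleaning
  stage thresholds later.
* **Canonical forms.** K-mers are stored as the lexicographic minimum
  of the sequence and its reverse complement; the graph is bidirected
  (links attach to node *sides*), so each double-stranded sequence is
  stored once and assembling the reverse-complemented read set yields
  the same contigs up to orientation.
* **Hairpin links.** A palindromic (k−1)-flank would link a node's end
  to itself on the opposite strand; such fold-backs cannot be traversed
  by a read and are dropped at construction. Genuine same-orientation
  self-overlaps (tandem/circular structure) are kept.
* **`cs` binding.** The spectral cutoff is applied both to link
  frequencies and to isolated-node coverage, the two places where a
  low-support object can survive into contigs.
* **Split scan order and `-hp`.** Whether the original formulation
  splits on one or all qualifying columns at once is unspecified;
  first-hit scanning with recursion is fixed here. The CLI exposes `sp`
  as `-hp`, whose published values (0.6, 0.8) match the splitting
  threshold's range.
* **Ns in reads.** Reads are split at non-ACGT characters into
  fragments before k-mer extraction; fragments shorter than k are
  dropped. The method is defined over {A,C,G,T} only.
* **Negative scaffold gaps** are not merged; a single `N` marks the
  junction, keeping every non-N scaffold character a verbatim contig
  substring.
* **Threading threshold.** Junction resolution demands unanimity and at
  least two spanning reads per pairing — conservative, so repeats are
  broken rather than mis-joined when evidence is thin.

## What the simulator emulates — and what it does not

`random_genome()` and `simulate_read_pairs()` produce i.i.d. genomes
(optionally with planted exact repeats) and inward-facing paired reads
with Gaussian insert lengths, uniform start and strand, and uniform
substitution errors at a constant rate — the error structure the method
is designed for. They do **not** model indels, position-dependent
quality, coverage bias, PCR duplicates or heterozygosity. Passing tests
on these fixtures therefore demonstrates the algorithmic properties
(oracle-exact clustering, denoising, recovery, scaffolding geometry,
determinism) but not robustness to real-library artefacts; on real data
one would error-correct and adapter-trim upstream, which composes
cleanly since clustering operates on whatever reads it is given.

Problem sizes in the test-suite and acceptance runs — 20–30 kb genomes
at 30× coverage, 200 random clustering instances of up to 500 k-mers —
were chosen so the whole suite exercises every stage, including two
full assemblies of the same erroneous read set, in a few minutes on one
core. The properties checked (component equality with a brute-force
union-find oracle, pigeonhole recall, single-contig recovery, gap
accuracy within sampling error of the insert distribution) are
size-independent statements.

## Numerical and degenerate-input behaviour

Empty inputs give empty tables and graphs rather than errors, except
where a precondition is violated (mismatched pair files, k < p + 1,
sp outside (0, 1], m > k − 1), which fail before any computation. A k
larger than every read fragment yields an empty k-mer table with a
warning. Gap estimates use the lower-middle median, so even support
counts do not interpolate. Coverage of merged unitigs is the
k-mer-count-weighted mean of the parts.

## Known limitations

Everything is held in memory; the practical ceiling on one core is
megabase-scale genomes. Clustering cost grows with the candidate
stream, which degrades for highly repetitive or extremely low-complexity
sequence (large pigeonhole buckets). Indel errors are out of scope by
design. Scaffolding handles nested libraries shortest-insert first but
does not perform gap filling, and mate-pair (outward) libraries are
supported only by mate swapping in the simulator (`orientation =
"rf"`).

## A compact demonstration

```{r demo, eval = FALSE}
genome <- random_genome(20000, seed = 101)
reads  <- simulate_read_pairs(genome, read_length = 100, coverage = 30,
                              error_rate = 0.01, insert_mean = 300,
                              insert_sd = 30, seed = 102)
tab  <- extract_kmers(reads, 21)
cons <- build_consensus_set(cluster_kmers(tab, 1), sp = 0.6)
c(raw = nrow(tab$counts), consensus = nrow(cons$nodes))

res <- run_assembly(reads = reads, k = 21, p = 1, cs = 5,
                    out_prefix = NULL)
res$contig_stats
```

At 1% errors roughly three quarters of the distinct raw 21-mers are
error satellites; clustering absorbs them into their true centres and
the genome assembles into a single contig. The acceptance script
(`scripts/acceptance.R`) reruns this and the other headline
computations end to end and writes the measured values as JSON.
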