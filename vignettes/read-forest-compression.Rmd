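---
title: "Read-forest compression: model, codec and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-forest compression: model, codec and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readforest)
```

## The model and its assumptions

`readforest` compresses a *multiset* of fixed-length DNA reads. Two
modelling assumptions shape everything else:

* **Order is information-free.** Read order in a FASTQ file reflects the
  instrument, not the sample, so the compressor may reorganise reads and
  decompression returns an unordered multiset.
* **Reads are redundant.** Reads drawn from the same genome overlap; the
  shared bases should be stored once.

A **read forest** captures the redundancy with a single pointer per read:
each distinct read `v` keeps at most one edge to a parent `π(v)` whose
suffix covers `v`'s prefix, with edge weight `w(v, π(v)) = L − overlap`
(roots pay `L`). The total edge weight equals the number of consensus
symbols stored, so minimising weight minimises the dominant stream of the
archive. Since every node has out-degree ≤ 1, each component holds at most
one cycle; components are *cycle-rooted tries*.

The builder (`build_read_forest()`) processes reads in input order. A new
read slides a length-`K` window right-to-left over itself, queries a
suffix `K`-mer index, and extends each hit allowing at most `eps`
mismatches *outside* the seed window, committing the first (longest)
validated parent. It then slides left-to-right against a prefix index and
adopts any existing node whose current edge is worse than what the new
read offers. Duplicates collapse to one node with multiplicity.

On error-free reads this greedy procedure is optimal: defining
`rep(v)` as the minimum achievable edge weight of `v` over all other
reads, any forest weighs at least `Σ rep(v)`, and the greedy forest
attains it. The test suite certifies this on hundreds of randomised
instances against `brute_rep_table()`, a deliberately naive oracle that
re-scans every overlap length by substring comparison, sharing no code
with the indexed builder. A second oracle, `brute_scs_length()`,
enumerates read permutations to verify the forest never stores more
symbols than the shortest common superstring.

Two certainties are deliberately *not* claimed. With `eps > 0` the
optimality proof does not apply (mismatch-tolerant extension can commit
edges exact matching would reject), so optimality tests run at `eps = 0`.
And the superstring bound is asserted only for `K = 1`: for `K > 1` the
forest is barred from overlaps shorter than `K` that a superstring may
freely use, and the bound genuinely fails on small instances — the
comparison is between unconstrained representations.

## Parameters

* **`K`** (minimum overlap / seed length; default `⌊L/5⌋`, e.g. 20 for
  101-base reads). Larger `K` speeds up search but forfeits short
  overlaps; the default keeps the seed long enough for near-constant hash
  bucket loads on typical coverages while accepting overlaps down to a
  fifth of the read.
* **`eps`** (mismatches tolerated outside the seed; default 2). Sequencing
  errors destroy exact overlaps; allowing a couple of mismatches per
  extension recovers most of them at negligible risk of spurious joins
  given the exact `K`-seed requirement.
* **`strand_correct`** (default off). Reads arrive from either strand; the
  greedy heuristic tries both orientations during the parent search and
  commits the one with the longer validated overlap. Once committed, a
  node's orientation never changes, even if its parent is later
  reassigned.

## The container

`encode_container()` decomposes the forest into contigs: starting from
each unprocessed leaf it walks parent links until reaching a root, an
already-processed node, or a node on the current path. The last case
closes a cycle; the cycle is emitted as its own contig (parent = itself)
and the walked tail as a separate contig referencing it. Pure cycles with
no attached tree are collected afterwards. This ordering guarantees every
parent reference points backwards, so decoding is single-pass.

Per contig the archive stores: read count; a parent pointer (Elias-gamma
distance to the parent contig, plus the attachment read's index in
`⌈log2 n⌉` bits); the per-read differential offsets — each read's edge
weight, whose sum is exactly the contig consensus length — coded with a
canonical Huffman codebook over `{1..L}` built from the fixed truncated
geometric profile `P(d) ∝ 0.85^(d−1)`, derived identically by encoder and
decoder from `L` alone; and per-read mismatch records (gamma count, then
`⌈log2 L⌉`-bit offset + 2-bit base each). Consensus symbols are 2-bit
packed and post-compressed with DEFLATE. Reads that found neither parent
nor child travel in a separate singleton stream as raw 2-bit reads.
Side streams carry multiplicities (gamma) and the true positions of `N`
symbols. Byte order is little-endian; the magic is `ATRF`.

Reconstruction places read `i` of a contig at consensus positions
`(Σ_{j≤i} d_j − L) … (Σ_{j≤i} d_j − 1)`, borrowing negative positions
from the parent read's reconstructed string; cycle contigs index modulo
the consensus length. Mismatch records are computed by the encoder against
exactly the string the decoder will derive (the parent side wins inside
overlaps; no majority consensus is ever computed), which makes
losslessness structural rather than statistical: `decode(encode(R)) == R`
as a multiset for *any* valid input, including stacked errors, `N`s,
duplicates and strand-flipped reads.

Numerical and convention choices worth recording:

* Offsets and intervals are 0-based half-open; `N` offsets refer to the
  committed orientation of the node.
* `N` is replaced by the placeholder `A` *before* orientation, so on a
  reverse-committed node the placeholder appears as `T` in oriented
  coordinates; the `N` stream restores truth either way.
* Parent overlaps are capped at `L − 1` (edge weights live in `[1, L]`,
  matching the delta codebook); a full-length overlap between distinct
  nodes can only arise via `N`-placeholder collisions or `eps > 0` and is
  simply not taken.
* Ties among equal-overlap candidates go to the earliest-inserted node;
  children are reassigned at most once per integration step; candidate
  validation uses the same rule in both search directions (exact `K` seed
  at the overlap end, `≤ eps` mismatches elsewhere), which keeps the edge
  invariant uniform — for `eps = 0` this is exactly the textbook search,
  for `eps > 0` it is marginally stricter on the children side than a
  prefix-seed-only reading would be.
* A node records separate forward/reverse multiplicities: with strand
  correction a read and its reverse complement may collapse onto one
  node while needing to be re-emitted in both orientations, which a
  single per-node flag cannot express.
* The codebook's geometric decay 0.85 reflects the empirical shape of
  edge-weight distributions at moderate coverage (most deltas are small);
  any shared deterministic codebook would be correct, this one is merely
  compact.

## The entropy approximation

`estimate_read_set_entropy()` evaluates

```
H(R) ≈ N·L·log2(3)·h2(p) + |G|·H(Poisson(N/|G|)) + LZ(G)
```

— the error-process term (`h2` the binary entropy), the read-sampling
term (Poisson position counts at mean coverage `N/|G|`), and the genome
descriptive-complexity term, estimated by the size of a maximum-setting
gzip file of the genome text. The remaining conditional terms of the
exact decomposition are treated as zero: with assembly-grade coverage the
genome is recoverable from the reads up to contig arrangement, and read
locations are recoverable by mapping. The Poisson entropy series is
truncated where the tail contributes far less than 1e-12 bits, orders of
magnitude below the 3-decimal reporting precision.

Two caveats. The gzip backend makes the absolute `LZ(G)` value
backend-dependent (pinned here to R's zlib at level 9). And the
three-term sum is an *approximation*, not a certified bound in both
directions: on uniform random genomes gzip spends ≈ 2.37 bits/base where
a 2-bit packer spends 2.0, so at moderate coverage (≈ 20x) the
approximation can sit a few thousandths of a bit/base *above* what the
compressor achieves on error-free reads; at 40x — a coverage typical of
bacterial resequencing — the compressor's per-read overheads dominate
and the approximation lower-bounds the achieved rate as intended. The
package's high-coverage check therefore runs at 40x, and the 20x
behaviour is reported as measured.

## The simulator, and what passing tests do not show

`simulate_genome()` / `sample_reads()` emulate exactly the model above:
uniform i.i.d. genome, uniform read starts on a linear genome (positions
`[0, |G| − L]`; edge effects are negligible for `|G| ≫ L`), i.i.d.
substitutions (uniform over the other three bases — the dominant Illumina
error mode; indels are out of scope), optional strand flips, all driven by
R's Mersenne-Twister from a single seed for byte-reproducible fixtures.

Real data differ in ways the simulator deliberately omits: genomic
repeats (which create spurious overlap candidates and real cycles),
position-dependent error rates, coverage biases, and paired-end
structure. Passing tests therefore certify the combinatorial claims and
losslessness — which hold for arbitrary inputs — but compression *rates*
measured on simulated data should not be read as predictions for real
libraries.

## Problem sizes used by the test suite

Optimality is certified on 200 randomised instances (genomes 2–20 kb,
`L ∈ {20, 50, 100}`, coverage 2–20x, `K = ⌊L/5⌋`, `eps = 0`); the
superstring bound on 500 instances of up to 7 distinct reads; round-trip
losslessness across the full parameter grid at moderate size plus one
50,000-read, 100 kb-genome cell; and the entropy-gap behaviour at 20x on
a 100 kb genome over `p ∈ {0, 0.002, 0.01, 0.02}` with three seeds per
rate. These sizes exercise every code path (cycles, tails, singletons,
`N`s, duplicates, both strands) while keeping the whole suite in the
low minutes on one core.

## Known limitations

* Fixed-length reads only; variable-length input is rejected rather than
  padded.
* Encoding is in-memory, single-threaded, without random access into the
  container.
* Optimality is a statement about *symbol counts* under the read-forest
  representation; it does not imply bitwise optimality of the final
  archive.
* At low coverage on uniform random genomes the entropy approximation can
  slightly exceed the achieved rate (see above) — a property of the
  gzip-based genome term, not of the codec.
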