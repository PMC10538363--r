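---
title: "Constructing compacted and colored de Bruijn graphs with unitigr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing compacted and colored de Bruijn graphs with unitigr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitigr)
```

## The problem

A de Bruijn graph of order *k* over a sequence collection *R* has the
(*k*−1)-mers of *R* as nodes and its *k*-mers as edges (the *edge-centric*
view). Collapsing every non-branching path yields the *compacted* graph,
whose maximal unitigs are the standard substrate for assembly, pangenomics
and k-mer indexing. When reverse complements are identified — a k-mer and
its reverse complement are one object — the target is the set of
*canonical maximal unitigs*: a set *U* of strings such that

1. every string has length ≥ *k* and no two are reverse complements of each
   other;
2. a k-mer *q* has canonical abundance ≥ *a* in *R* exactly when *q* occurs
   (canonically) in *U* — with abundance threshold *a* rare (noise) k-mers
   are excluded;
3. a (*k*−1)-mer occurring canonically more than once in *U* occurs only as
   a prefix or suffix (unitigs never span branching nodes); and
4. every unitig end is branching, a source, or a sink (maximality).

`unitigr` builds this set — optionally *colored*, i.e. annotated per k-mer
with the subset of input files containing it — and answers batch k-mer
membership queries against the result. A brute-force reference oracle
implementing the definition directly, plus seeded synthetic-data
generators, back the test suite.

## The construction pipeline

The algorithm avoids one global k-mer table; instead it partitions work so
every piece of the graph can be built from a small, self-contained group of
input fragments, and repairs the seams afterwards.

**Read splitting.** For a rolling hash over *m*-mers (`m = max(1, min(12,
k-2))` by default), the *minimizer* of a (*k*−1)-mer is the minimum hash
over its *k*−*m* constituent m-mers — a position-free value. Every input
sequence is cut into *super-(k−1)-mers*: maximal runs of consecutive
(*k*−1)-mers sharing one minimizer. Consecutive segments overlap on *k*−2
characters; after attaching the single *linking characters* that flank a
segment in its read, consecutive extended segments overlap on exactly *k*
characters. Each extended segment is filed under the *group* of its
minimizer; groups are packed into a bounded number of bucket files. Three
facts make this sound: a k-mer occurs in at most two groups (two exactly
when its prefix- and suffix-(*k*−1)-mer minimizers differ, i.e. when it
straddles a segment boundary — equivalently, when it covers a linking
character); its abundance within a group equals its abundance in *R*; and
all (*k*−1)-overlap neighbors of a non-straddling k-mer are present in its
group.

**Per-group counting and extension.** Each group is k-mer counted into a
table of canonical k-mers carrying abundance, a linking flag, and the
window minimizers of the k-mer's two end (*k*−1)-mers. After abundance
filtering, unitigs are grown from unconsumed seeds: a step right is taken
only when exactly one of the four forward candidate k-mers is present *and*
that candidate has exactly one backward candidate; growth on a side stops
when the terminal k-mer's outward window minimizer leaves the group — the
continuation belongs to the k-mer's other group — and that stop emits an
*endpoint record* (canonical end k-mer, unitig id, side, orientation).
Counting and extension are strictly per group even when several groups
share a bucket file; counting per bucket would double-count straddling
k-mers and break the abundance filter. In-group cycles (a walk returning to
its seed) close immediately and emit no records.

A subtlety worth documenting: a linking-flagged k-mer may be *seeded*
before a neighbor consumes it. Stopping purely on the link flag would then
emit records on both sides of a lone seed and break the exactly-two-records
invariant. The implementation therefore stops (and emits a record) on a
side exactly when the outward window minimizer differs from the group
minimizer; a lone boundary seed emits exactly one record, on the side whose
continuation lives in its other group, and may still extend on its reliable
side. Non-boundary k-mers seed first (deterministic order) so chains
consume their boundary k-mers naturally.

**Randomized seal-and-merge.** Every boundary k-mer ends up with exactly
two endpoint records, contributed by its two groups. Pairing them yields
two-unitig chains overlapping on *k* characters (the duplicated boundary
k-mer), orientation-resolved by junction-text equality so unitigs read in
opposite strands are reverse-complemented before joining. Chains that share
a terminal unitig id must be concatenated; instead of a union-find, each
round every pending chain picks one of its unsealed ends uniformly at
random and files itself under that end's bucket, leaving a placeholder for
its other (unsealed) end. Two chains filed under the same terminal id
concatenate; a filed ending with no partner and no placeholder is *sealed*;
chains with both ends sealed are final; a chain whose head id meets its
tail closes into a cycle. For a worst-case pair (both chains fully
unsealed) the two chains pick the shared ending together with probability
1/4, so the expected number of rounds until such a pair joins is 4
(geometric); the package's `simulate_merge_pairs()` and
`simulate_merge_rounds()` reproduce both numbers, holding the outer ends
unsealed throughout as the worst case requires. The final unitig *set* is
independent of the seed; only round counts vary (tested across ten seeds).

**Output normalization.** Linear unitigs are reported as the lexicographic
minimum of spelling and reverse complement; cycles as the least
linearization over all rotations and both strands, carrying their
(*k*−1)-wrap. This makes output sets diffable and comparable.

## Coloring

With one color per input file (ids 0,1,… in input order), each k-mer's
normalized color list (sorted, deduplicated) is interned: the
delta-of-sorted-ids, run-length-encoded byte form is hashed with a 128-bit
digest into a global map from digest to dense *subset index*; a hit is
deep-compared so a digest collision is a detected hard error rather than a
silent merge. A k-mer counted in two groups derives the same color set in
both (its in-group occurrences are its global occurrences); this is
asserted when the global k-mer-to-index map is filled. Final unitig headers
carry the per-k-mer subset indices run-length encoded
(`>u<id> C:<idx>:<len>,...`), computed by scanning the merged strings
against the global map — equivalent to, but much simpler than, flipping and
rotating per-fragment index runs through the merge. The color map persists
as independently compressed chunks (1024 sets per chunk by default) of the
delta+RLE encodings.

The abundance threshold in colored mode counts occurrences pooled across
all files, matching the color-agnostic definition above.

## Querying

`query_batch()` counts, per query, the positions whose canonical k-mer
occurs in the graph — duplicated query k-mers count once per *position*
(the alternative, counting distinct k-mers, changes results and is not
offered). Colored graphs additionally report, per color, the matched
positions whose k-mer's color set contains that color (positive counts
only). The default computation partitions graph and query k-mers by k-mer
minimizer into buckets and sums per-bucket counts, mirroring construction;
it is verified to equal the single-table computation and a naive
per-position oracle. Uncolored results serialize to CSV (match percentage
at two decimals, `0.00` for queries shorter than *k*); colored results to
JSON Lines. A match-percentage threshold filters reported queries.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | — | k-mer size (≥ 2); any value is accepted, odd k avoids palindromic k-mers |
| `a` | 1 | minimum canonical k-mer abundance |
| `m` | `max(1, min(12, k-2))` | minimizer length; affects only group balance, never the output (tested) |
| `hash_name` | `"mix"` | m-mer hash; `"mix2"` for independence checks, `"rank"` (the base-4 code) for worked examples |
| `n_buckets` | 256 | bucket files for segments (power of two; low bits of the minimizer) |
| `merge_buckets` | 64 | buckets of the randomized merge (keyed by terminal unitig id) |
| `seed` | 1 | drives only the randomized merge rounds |
| `long_k_hash` | `k > 64` | key the counting table by a 128-bit Rabin–Karp digest of each canonical k-mer (primes 2/3/5/7 as base codes, polynomial over 2^128); collisions are detected (warning) but not corrected |

## Numerical and design choices

* **Canonical representative**: lexicographic minimum of a string and its
  reverse complement; palindromes are forward. Minimizer ties need no
  tie-breaking because the minimizer is the hash value itself, not a
  position.
* **Non-ACGT input**: records are split into maximal A/C/G/T runs; runs
  shorter than k are dropped and counted.
* **Sentinels**: linking characters absent at read ends are represented by
  absence flags; no `$` character is materialized.
* **Degenerate inputs**: reads shorter than k are skipped with a count; an
  input with no usable run yields an empty graph object.
* **Palindromic (k−1)-mer ends** (even k−1): at such an end the incoming
  edge reappears reversed among the outgoing candidates, so the literal
  maximality counts read 1 although the only continuation would re-use that
  edge; both the pipeline and the oracle stop there, and the condition
  checker exempts these ends (as it exempts cycle ends, whose wrap makes
  them formally extendable).
* **Merge keying**: chains join on terminal unitig *ids* (the two chains
  sharing a terminal reach it via its two different extremities, so an
  id-keyed bucket is the only key under which they meet).
* **Determinism**: seeds are consumed through a scoped RNG that restores
  the caller's random state; seed order of unitig extension is
  deterministic (non-boundary k-mers first, then lexicographic), so builds
  are reproducible bit-for-bit.

## What the synthetic data does and does not cover

The generators produce uniform i.i.d. genomes, substitution-only reads
(deterministic tiling for k-mer closure plus uniform random reads, per-read
reverse complementing), multi-color collections with a shared backbone and
private segments kept as separate records (so expected color sets are known
exactly), and adversarial cases: a linearized circular sequence, exact
tandem repeats, low-complexity sequence (minimizer runs collapse), a
palindrome-bearing sequence for even k, and reads shorter than k. Real data
differ in ways these fixtures do not model: biased base composition,
structured repeat families, indel errors, and quality-dependent error
profiles. Passing tests therefore demonstrate *algorithmic correctness of
the construction on arbitrary k-mer spectra of this kind*, not robustness
of any error-correction heuristics (there are none: abundance filtering is
the only noise control, as in the definition).

## Verification strategy and problem sizes

The oracle (`maximal_unitigs_bruteforce()`) computes unitigs directly from
the definition on the global k-mer set — no groups, no linking characters,
no merging — and is kept structurally independent of the pipeline. The test
suite compares the two on 200 random fixtures (genomes 1–50 kb, k in
{5, 15, 21, 31, 63}, a in {1, 2}, genomes and error-bearing reads) plus all
adversarial fixtures, asserts the four defining conditions on pipeline
outputs, checks the three splitting guarantees by brute-force occurrence
counting, exercises the supplementary equivalence between edge-centric and
node-centric unitig constructions, and validates colors and queries against
naive oracles (including 10^4 codec round-trips and 100 query batches).
Monte-Carlo checks of the merge procedure use 10^5 replicates
(join-probability tolerance ±0.01, expected-rounds tolerance ±0.05). The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
at a reduced fixture count (60 random fixtures) chosen to keep a
single-CPU run in the minutes range.

## Known limitations

* Throughput: the implementation is a single-process, in-memory R
  realization of an algorithm designed for parallel, out-of-core execution;
  it is meant for method study and moderate inputs, not hundred-gigabyte
  collections.
* The hashed long-k representation detects digest collisions but, like the
  scheme it implements, cannot correct them.
* Cycle normalization enumerates rotations and is quadratic in cycle
  length; cycles above 20 000 edges are refused rather than silently slow.
* Orientation resolution at palindromic junction k-mers covers the cases
  the generators produce; doubly-palindromic hairpin chains (possible only
  for even k) fail loudly rather than merging incorrectly.
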