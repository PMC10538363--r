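# unitigr

Compacted — and optionally colored — de Bruijn graph construction and
querying in R, with a brute-force reference oracle and seeded synthetic-data
generators.

## What it does, and for whom

Given FASTA/FASTQ collections (reads or assembled genomes), `unitigr`
computes the set of **canonical maximal unitigs** of the order-*k* de Bruijn
graph: the strings *U* such that

* every string has length ≥ *k* and no two are reverse complements;
* a k-mer *q* satisfies occ<sub>cn</sub>(q, R) ≥ a ⟺ occ<sub>cn</sub>(q, U) ≥ 1,
  where occ<sub>cn</sub> pools occurrences of *q* and its reverse complement
  (palindromes counted once) and *a* is the abundance threshold;
* any (k−1)-mer with occ<sub>cn</sub>(q, U) > 1 occurs only as a prefix or
  suffix of strings in *U* (unitigs do not span branching nodes); and
* every unitig end is branching, a source, or a sink (maximality).

The construction follows the minimizer-bucketed strategy used by modern
compaction tools: sequences are split into super-(k−1)-mers sharing one
window minimizer, extended with *linking characters* so consecutive segments
overlap on exactly *k* characters; each minimizer group is independently
k-mer-counted and compacted into intermediate unitigs; and intermediate
unitigs are joined across groups by a randomized *seal-and-merge* procedure
(a worst-case pair of chains joins in a round with probability 1/4, hence 4
expected rounds) instead of a union-find. In colored mode each input file is
one color; per-k-mer color sets are deduplicated behind dense subset indices
via a 128-bit hash, stored delta+run-length encoded, and attached to unitig
FASTA headers as index runs. Batch queries report per-query (and per-color)
matched k-mer counts, as CSV or JSON Lines.

It is intended for method study, teaching, and moderate-size analyses in R —
not as a competitor to compiled tools on hundred-gigabyte collections.

## Worked example

```r
library(unitigr)

# two related "strains": a shared backbone plus private segments
cc <- color_collection(n_colors = 2, shared_fraction = 0.5,
                       backbone_len = 400, seed = 8)
g <- dbg_build(cc, k = 21, colored = TRUE, seed = 1)
g
#> Compacted de Bruijn graph (k = 21 , a = 1 , canonical )
#>   unitigs:   3 (0 cyclic)
#>   k-mers:    1366
#>   colors:    2 (3 distinct color sets)
#>   merge:     229 intermediate unitigs, 12 rounds
```

Three unitigs: the backbone (present in both colors) and one private unitig
per color; three interned color sets ({0,1}, {0}, {1}). Querying a slice of
the backbone and a random sequence:

```r
res <- query_batch(g, c(hit = substring(attr(cc, "backbone"), 5, 104),
                        rand = random_genome(60, seed = 999)))
res[, c("query_id", "total_kmers", "matched", "percent")]
#>   query_id total_kmers matched percent
#> 1      hit          80      80     100
#> 2     rand          40       0       0
res$per_color[[1]]
#>  0  1
#> 80 80
```

All 80 k-mers of the backbone slice match, in both colors; the random query
matches nothing. `write_query_csv()` / `write_query_jsonl()` serialize
these results; `save_cdbg()` / `load_cdbg()` persist the graph (unitig
FASTA with color-run headers, JSON metadata, chunked binary color map).

Every construction claim is testable against the included oracle:

```r
identical(g$unitigs, maximal_unitigs_bruteforce(unlist(cc), 21))
#> [1] TRUE
```

A command-line wrapper is installed with the package:

```sh
$(Rscript -e 'cat(system.file("exec", "unitigr", package = "unitigr"))') \
    build -k 21 --colors -o graph c0.fa c1.fa.gz
... query --graph graph --queries queries.fa -o hits.jsonl
```

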