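Package: unitigr
Title: Compacted and Colored De Bruijn Graph Construction with Minimizer
    Bucketing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compacted, optionally colored, de Bruijn graphs from
    FASTA/FASTQ collections using minimizer-based super-(k-1)-mer splitting
    with linking characters, per-group k-mer counting and bidirectional
    unitig extension, and a randomized seal-and-merge procedure that joins
    intermediate unitigs across groups into maximal canonical unitigs.
    Colored graphs intern deduplicated color sets behind run-length encoded
    indices; batch k-mer membership queries report per-query (and per-color)
    match counts. A brute-force reference oracle implementing the
    string-centric definition of canonical maximal unitigs, plus seeded
    synthetic-data generators, back the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
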