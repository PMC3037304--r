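Package: ssrmine
Title: EST-SSR Mining, Survey Statistics and In Silico Marker Transferability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects class I perfect microsatellites (simple sequence
    repeats, SSRs) in EST/cDNA FASTA databases, eliminates overlapping
    repeat calls, partitions loci into single and compound SSRs, and labels
    motifs by canonical reverse-complement pairs. Computes comparative
    survey statistics across databases (locus counts, SSR/EST incidence,
    motif-length spectra, canonical motif frequency tables), predicts the
    amino acids encoded by trimer, hexamer and nonamer motifs, and relates
    motif frequencies to codon-usage bias via GC1/GC2/GC3 statistics.
    Assesses cross-species marker transferability by in-silico PCR with
    flanking-primer design, mismatch-tolerant site scanning and a virtual
    gel report. Includes a synthetic EST database generator with planted
    repeat tracts and derived ortholog databases for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
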