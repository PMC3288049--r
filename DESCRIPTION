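Package: maeval
Title: Model-Assembly Evaluation of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-based benchmarking of de novo transcriptome
    assemblies from 454-style pyrosequencing reads. Simulates an expression
    library (Zipf-law expression, reverse transcription with transcription
    start site jitter, Poisson-process mechanical fragmentation, size
    selection, subsampling) and flow-cycle pyrosequencing with a
    homopolymer-scaled error model, keeping the exact transcript origin of
    every read. From the origin-tagged reads it constructs the Model
    Assembly, the positionally optimal assembly obtained by merging
    common-origin reads that overlap by at least one base pair, and scores
    any assembly against it: basic contig statistics (N50, length
    distributions), alignment-based containment specificity and
    sensitivity, read-mapping ambiguity, and chimera formation quantified
    through read provenance, split by alternative-splicing status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
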