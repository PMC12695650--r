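Package: strandkaryo
Title: De Novo Chromosomal Abnormality Calling and Rate Modelling from
    Single-Cell Strand-Resolved Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls and classifies de novo chromosomal abnormalities (CAs)
    from binned, strand-resolved single-cell sequencing counts of the
    Strand-seq type. Provides a synthetic population generator with known
    karyotypes, template-strand states, sister-chromatid exchanges and
    injected CA events; haplotype-aware joint segmentation of read depth
    and Watson/Crick composition against a population consensus; a CA
    taxonomy classifier (whole-chromosome, terminal, interstitial,
    terminal multi-step, complex and chromothripsis, with inverted
    duplication, whole-arm, amplification and isoacentric annotations);
    sister-cell pair identification from reciprocal template-strand
    inheritance and mirrored sister-chromatid exchanges; an agent-based
    model of a growing cell population for estimating per-mitosis-type CA
    mutation rates; and the exact and resampling statistics used in CA
    enrichment analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
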