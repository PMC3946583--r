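Package: tescan
Title: Transcriptome-Based Transposable Element Discovery, Expression
    Profiling and Copy-Number Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers transposable elements (TEs) in assembled
    transcriptomes by keyword, homology and sub-terminal motif screening,
    classifies them under the Wicker taxonomy (with a hairpin-based
    Helitron criterion), profiles their expression from read counts
    (RPKM) and NlaIII CATG digital gene expression tags (TPM), calls
    differentially and specifically expressed TEs with an exact
    hypergeometric test, estimates gene copy number from real-time PCR
    standard curves, and compares predicted transcripts against cloned
    genomic sequences. A seeded synthetic-data generator with full
    ground truth makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
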