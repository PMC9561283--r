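Package: geotx
Title: Sub-Molecular Geographic Encodings of RNA Transcripts for Modification Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes the sub-molecular geography of RNA transcripts -- the layout of
    5'UTR, CDS, 3'UTR, exons and introns around a target ribonucleotide -- as compact
    feature representations (six landmark distances, equal-width grid compositions,
    maximal-run region chunks, and one-hot region/sequence matrices) for machine
    learning of RNA modification sites such as N6-methyladenosine (m6A). Provides
    transcript annotation ingestion with genome/transcript coordinate mapping,
    isoform-aware multiple instance learning with gated attention pooling and
    Noisy-OR read aggregation, a permutation-FDR procedure for multi-technique
    epitranscriptome concordance, and a seeded synthetic data generator emulating
    the geographic preferences of m6A (long exons, last exons, stop-codon proximity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
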