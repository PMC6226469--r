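Package: teloforge
Title: Chromosome-End Extension Analysis from Optical Maps and Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects, classifies and validates structural variation at chromosome
    ends (subtelomeric extensions, missing terminal sequence, terminal tandem
    expansions) from optical genome-mapping label data and long sequencing reads.
    Provides in-silico nicking-enzyme digestion and CMAP/XMAP-dialect input and
    output, a dynamic-programming label-map aligner with a sizing-error likelihood
    score, terminus anchoring and extension/missing calling against an inter-label
    distance threshold, trio inheritance testing, k-mer dotplot validation of
    predicted chimeric extensions with tandem repeat unit estimation, and detection
    and molecular-clock dating of subtelomeric segmental-duplication families.
    Includes a fully parameterised synthetic-data generator (reference genomes with
    planted duplication families, trio haplotypes with chromosome-end events, noisy
    contig label maps, error-bearing long reads, duplication-pair tables) carrying
    complete ground truth, so the whole pipeline can be exercised and scored end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
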