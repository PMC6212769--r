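Package: spaceracq
Title: CRISPR Spacer Acquisition Detection from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing naive CRISPR-Cas adaptation from
    amplicon sequencing of expanded CRISPR arrays. Implements Phred-threshold
    read trimming, approximate CRISPR-repeat detection with a Hamming mismatch
    allowance, extraction and identity deduplication of inter-repeat spacers,
    hierarchical plasmid-first exact mapping on circular references with
    discard of non-unique chromosomal matches, fixed-width regional enrichment
    statistics (origin, terminus and CRISPR-locus windows normalized to a
    reference window), strand-bias testing, and densitometry-based
    quantification of spacer acquisition from gel band intensities. A
    synthetic-data module generates reference sequences, expanded-array
    amplicons and error-bearing paired-end reads with known ground truth so
    the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
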