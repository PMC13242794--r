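Package: readtrim
Title: Composable Adapter and Quality Trimming for Illumina FASTQ Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A read-preprocessing engine for single-end and paired-end
    Illumina FASTQ data. Applies an ordered, colon-delimited list of
    trimming and filtering steps to each read or read pair: adapter
    clipping in simple and palindrome (read-through) mode, sliding-window
    and information-maximizing quality trimming, fixed-length cropping,
    average-quality and minimum-length filters. Handles plain, GZIP and
    BZIP2 compressed input, writes block-parallel multi-member GZIP
    output, auto-detects PHRED quality encoding (Phred33/Phred64),
    validates read-pair synchronization before processing, tracks the
    fate of every pair, and reports summary statistics and an optional
    per-read trim log. Includes a seeded synthetic paired-read simulator
    with known insert sizes and adapter read-through for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: zlib
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
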