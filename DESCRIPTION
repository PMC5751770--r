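Package: fqarc
Title: Block-Parallel Lossless FASTQ Compression with Random Access
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless, reference-free compression of FASTQ sequencing data.
    Records are split into metadata, base-sequence and quality-score
    sub-streams which are buffered into fixed-size blocks and compressed
    independently: bases with a Burrows-Wheeler transform followed by a mixed
    order-0/order-1 adaptive context model, quality scores with a multi-order
    (1/2/4/6) context-mixing model plus a matching model, and read identifiers
    with a hybrid tokenised codec (incremental digit coding, run-length-limited
    coding, self-delimiting varints, and a low-order fallback), all driven by a
    binary arithmetic coder. Compressed blocks are laid out in a nested
    container archive whose line-addressed index supports extraction of a
    record range without full decompression, and blocks can be streamed to an
    object sink while compression proceeds. A deterministic synthetic-FASTQ
    generator provides corpora with controlled read length, identifier
    structure and quality-alphabet size for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
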