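Package: lncsieve
Title: Identification and Characterization of Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained re-usable pipeline for genome-scale
    identification and characterization of long non-coding RNAs (lncRNAs)
    from assembled transcript models. Assigns cuffcompare-style class codes
    against a reference annotation, applies a non-coding filter cascade
    (length, coding potential, protein domains, housekeeping RNAs, mature
    miRNAs), classifies candidates by repeat content and small-RNA
    production into high-confidence lncRNAs, computes FPKM, tissue
    specificity (Jensen-Shannon score), pairwise differential expression,
    and screens for cis- and trans-acting candidate targets by expression
    correlation. Ships a deterministic synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
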