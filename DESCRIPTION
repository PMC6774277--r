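Package: rtsig
Title: Reverse-Transcription Signature Profiling and RNA Modification Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects reverse-transcription (RT) signatures of RNA modifications
    such as 1-methyladenosine (m1A) in aligned short-read sequencing data.
    Starting from samtools-style pileup text and a reference FASTA, the package
    trims residual C-tail overhang bases from read termini, computes
    per-position signature profiles (mismatch, arrest and jump rates with
    strand-split base counts), filters candidate modified sites either by
    single-sample thresholds or by the two-sample demethylation
    relative-change comparison, and trains a class-balanced random-forest
    caller with repeated cross-validated AUROC reporting. A seeded simulator
    generates references, reads and pileups with known signature parameters so
    the full pipeline can be validated offline, and a visualization module
    renders per-position signature plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
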