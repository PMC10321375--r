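Package: guidecraft
Title: Reference-Free CRISPR sgRNA Design with Genome-Wide Uniqueness
    and Off-Target Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design single-guide RNAs (sgRNAs) for any organism with a
    genome sequence, without relying on a pre-built reference species.
    Builds a genome-wide protospacer uniqueness database under a
    configurable PAM model, enumerates candidate guides from target
    sequences, detects potential off-target sites within a bounded
    number of base differences, scores them with a cutting frequency
    determination (CFD) style penalty model, computes per-guide quality
    features (GC content, poly-T/A runs, hairpin self-complementarity,
    a linear activity score), searches shared guides across gene groups
    for multiplex editing, extracts promoter/mRNA/CDS/UTR sequences
    from GFF3 annotation, designs verification primers, and emits
    ranked tab-separated reports with a position map. Includes a
    deterministic synthetic-genome fixture generator with planted on-
    and off-target sites for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    rtracklayer,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
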