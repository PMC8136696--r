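Package: chrominst
Title: Shallow Single-Cell Sequencing Pipeline for Preimplantation
    Aneuploidy Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for MALBAC-derived single-cell
    low-coverage whole-genome sequencing as used in preimplantation
    comprehensive chromosomal screening (PGT-A). Covers hexamer-index
    demultiplexing and read trimming, fixed-width genomic binning of
    unique mapped reads, per-1%-GC-stratum bias correction, the
    GC-corrected relative read number (RRN) on a copy-number scale,
    whole-chromosome aneuploidy calling with sex-aware baselines,
    per-sample and cohort QC metrics (read-fate rates, coefficient of
    variation, minimum-read adequacy), a base-composition diversity
    audit of library read prefixes, and a synthetic-data generator
    (toy references, overdispersed bin counts, structured FASTQ) with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    tools,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
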