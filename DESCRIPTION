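Package: droncqc
Title: Preprocessing, Barnyard QC and Droplet Simulation for
    Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational preprocessing and quality control for
    droplet-based single-nucleus RNA-seq (DroNc-seq) libraries: read-1
    structure validation (cell barcode, UMI, anchor base, poly-T),
    barcode whitelisting and Hamming-distance repair, UMI-collapsed
    expression quantification, species-mixing ("barnyard") doublet-rate
    estimation with the cross-species correction, Poisson droplet-loading
    arithmetic, read-region QC fractions, and nucleus-versus-cell
    expression concordance.  Includes a synthetic droplet-encapsulation
    generator (Poisson nucleus loading, two-species mixes, per-base
    barcode errors) that emits FASTQ and ground-truth tables, and an
    end-to-end pipeline with a machine-readable run report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
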