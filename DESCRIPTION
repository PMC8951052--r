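Package: kaspr
Title: Endpoint Fluorescence Genotyping, Assay Design and Purity Testing
    for Kompetitive Allele-Specific PCR (KASP)
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP genotyping with Kompetitive Allele-Specific PCR
    (KASP) endpoint fluorescence data. Reads two-dye (FAM/HEX) plate
    exports, normalizes each dye channel to percent fluorescence by the
    plate minimum and maximum, and calls genotypes from the polar angle of
    the normalized coordinates with a configurable no-amplification zone.
    Designs KASP primer trios (two tailed allele-specific primers plus a
    common primer) for bracketed-SNP templates under product-length and
    nearest-neighbor melting-temperature constraints, and validates
    existing trios. Models pooled-sample fluorescence as allele-dosage
    mixing to detect and estimate contamination of seed lots against pure
    reference lines, and combines multi-marker calls to classify single
    plants as restorer, hybrid, maintainer contaminant, or recombinant at
    a fertility-restorer locus. A seeded simulator generates synthetic
    plates with realistic cluster geometry for validation and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: SNP, Genetics, Sequencing, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
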