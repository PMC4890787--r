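Package: mbsv
Title: Mapping and Reconstruction of the Complex Structural Variant at the
    Chicken Muffs-and-Beard Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of the multi-stage analysis that mapped
    the chicken Muffs-and-beard (Mb) locus and reconstructed its causal
    complex structural variant. Provides synthetic-data generators (toy
    genomes carrying a three-segment duplication cassette, F2 intercrosses
    segregating a dominant locus, pooled read-depth tracks, junction-spanning
    reads, pyrosequencing signals, qPCR Ct tables); kinship-corrected
    association scans with conditional analysis and Bonferroni thresholds;
    line-origin HMM inference, linkage F-scans with randomization thresholds
    and shared identity-by-descent fine-mapping; windowed read-depth
    log2 fold-change CNV detection with mapping-quality filtering; breakpoint
    junction detection, microhomology/insertion classification and
    derived-allele assembly under copy-number constraints; copy-specific
    variant discovery, pyrosequencing dosage genotyping and in-silico
    diagnostic PCR; and 2^-ddCt relative-expression analysis with an
    Mb-consistent candidate-gene classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
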