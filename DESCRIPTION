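Package: panelsnp
Title: Design and Evaluation of SNP Fingerprinting Panels from Genotyping-Array Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-channel genotyping-array data for maize inbred and
    hybrid panels, calls genotypes against a per-locus cluster file in
    normalized theta/R space, scores locus clustering quality, runs a staged
    marker-selection pipeline (quality, data-quality, population, and
    designability gates) to assemble a DNA fingerprinting panel, and evaluates
    the panel with minor allele frequency spectra, parent-F1 pedigree
    consistency, pairwise differential-locus distributions, cross-platform
    concordance, and genomic distribution summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
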