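Package: snpms
Title: Single-Base-Extension SNP Mass-Spectrometry Genotyping of Mixed
    Fungal Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for iPLEX-style single-base-extension SNP genotyping of
    coexisting ITS genotypes by MALDI-TOF mass spectrometry, built around
    the marker system used for Ophiocordyceps sinensis in natural Cordyceps
    sinensis. Provides a genotype sequence registry with GC/AT-bias
    metadata, a packaged two-step assay panel (first-step PCR primer pairs
    and extension primers) with per-genotype allele prediction and
    extension-product mass calculation, a seeded simulator for genotype
    mixtures, biased amplification and mass spectra, allele-peak
    quantification with explicit missing-peak semantics,
    internal-reference intensity-ratio tables with fold-change arrow
    classification, and a stratified inference step that bounds each
    genotype group's share of the amplicon pool under presence constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    boot,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
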