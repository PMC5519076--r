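Package: snpcore
Title: Greedy Core Collection Selection from SNP Genotype Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects compact, reproducible core collections from large SNP
    genotype datasets by greedily maximizing a frequency-weighted genotype-class
    coverage score, with a diversity-score tie-break, removal of genetically
    identical samples, and dual stopping rules (target coverage or minimum
    per-step coverage gain). Includes evaluation statistics for any sample
    subset (class coverage CV, Shannon diversity over reference-allele
    frequencies, mean and minimum modified Rogers distance, allele-frequency
    spectra), readers and writers for delimited genotype matrices and VCF, a
    synthetic genotype simulator with founder structure, duplication, a tunable
    minor-allele-frequency spectrum and missingness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
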