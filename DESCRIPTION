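Package: cfduplex
Title: Duplex-Barcode Consensus Calling and Copy-Number Analysis for
    Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for ultra-high-specificity
    detection of low-fraction somatic variants and focal gene
    amplifications in cell-free DNA (cfDNA). Implements duplex-barcode
    digitization of sequencing reads into unique progenitor molecules
    (read-family grouping, per-strand consensus, duplex comparison),
    per-base background noise baselines trained on normal cohorts,
    consensus-based SNV calling with mutant-allele-fraction
    quantification and uncertainty bins, and unique-molecule copy-number
    calling with z-score amplification tests.  A synthetic cfDNA
    simulator (166-bp duplex fragments, heptamer strand barcodes, PCR
    duplication and jackpot errors, sequencing errors, genomic-DNA
    contamination, tumor-fraction spike-ins, focal amplification)
    supports in-silico analytic validation: dilution-series limit of
    detection, spike-in accuracy studies with exact binomial confidence
    intervals, split-sample concordance, and CNV limit-of-detection
    surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
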