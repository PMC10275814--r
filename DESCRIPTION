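Package: barquant
Title: Simulation, Extraction and Quantification of Random DNA Barcode
    Amplicon Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for chromosomally integrated random DNA barcode
    (lineage-tracking) amplicon sequencing. Simulates paired-end reads of
    barcode amplicons with realistic noise (library skew, PCR amplification
    bias with unique molecular identifiers, heterospacers, barcode-free
    ancestral contamination, substitution and indel sequencing error),
    merges read pairs with a quality-aware overlap consensus, extracts
    barcodes between conserved flanking anchors with a length filter,
    builds per-sample count tables with optional UMI collapse and
    error-aware directional clustering, and assesses library diversity and
    replicate reproducibility (length spectra, UpSet-style intersections,
    pairwise Pearson correlations, Shannon diversity, frequency
    trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
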