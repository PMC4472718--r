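Package: apctools
Title: Design and Validation of Multiplex PCR Panels and Artificial Positive Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and validating multiplex endpoint PCR and
    TaqMan qPCR species-identification panels and their synthetic multi-target
    artificial positive controls (APCs). Provides nearest-neighbor oligo
    thermodynamics (melting temperature, self- and cross-dimer scores, a
    single-stem hairpin free-energy screen), in-silico PCR amplicon prediction
    with a virtual gel, fluorophore-to-channel assignment by emission spectra,
    APC construct layout with nested per-target assay blocks and screened
    barcode spacers, GenBank/FASTA export, and qPCR standard-curve analytics
    (slope, R-squared, amplification efficiency, detection limit) over
    dilution-series Ct data. Ships the oligo panel and dilution-series tables
    for a five-species Liposcelis (psocid) diagnostic assay as worked data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
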