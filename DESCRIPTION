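Package: hrmid
Title: PCR High-Resolution Melting Species Identification for Necrophilous Flies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale toolkit for DNA-barcode species identification of
    necrophilous flies by PCR high-resolution melting (HRM). Screens primer
    candidates against conservation profiles of aligned COXI/COXII barcode
    panels, runs mismatch-tolerant in-silico PCR, predicts amplicon melting
    temperatures with nearest-neighbor duplex thermodynamics, simulates
    saturation-dye melt curves over the 65-90 degree ramp with derivative
    peak calling, and assigns unknown samples against reference Tm panels
    using a 0.15 degree Celsius decision rule with explicit ambiguity
    reporting. Includes deterministic bench-planning calculators for the
    reaction mix, template quantity, and thermocycler program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
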