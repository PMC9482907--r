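Package: napsri
Title: Retention-Time Indexing for Reversed-Phase LC-MS with NAPS Standards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts liquid-chromatography retention times to retention
    indices (RI) using a homologous series of N-alkylpyridinium-3-sulfonate
    (NAPS) reference standards. Provides exact-mass calculation of NAPS
    adducts and diagnostic fragments, calibration models (linear, natural
    cubic spline, Akima spline) mapping retention time to retention index
    and back, construction of RI libraries from replicate standard runs,
    metabolite annotation by combined m/z and RI tolerance matching, and
    quantification of NAPS-induced ion suppression in spiked biological
    matrices. A linear-solvent-strength gradient-elution simulator generates
    realistic synthetic data so the whole workflow is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
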