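Package: chelation
Title: Free Metal Ion Speciation in Chelator Buffers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes free (or required total) metal ion concentrations in
    buffers containing chelators such as EGTA, EDTA and ATP.  Absolute
    stability constants from four built-in sources (or user-supplied JSON)
    are converted to apparent association constants at the working
    temperature, pH and ionic equivalence via van't Hoff and extended
    Debye-Hueckel corrections with proton competition, and the coupled
    metal-ligand mass-balance system is solved by damped fixed-point
    iteration.  Includes an arbitrary-precision decimal arithmetic context,
    chelator purity correction, pX output, unit handling from molar to
    nanomolar, session accumulation with spreadsheet export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
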