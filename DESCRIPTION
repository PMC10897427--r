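Package: ipanr
Title: Quantification and Simulation of Interplanar Microtubule Network
    Dynamics in Apposed Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the dynamics of interplanar microtubule
    (MT) protrusion networks that link the dorsal and ventral epithelia of the
    Drosophila pupal wing, and for simulating ground-truthed synthetic 4D
    two-channel live-imaging experiments of that system. Implements the
    z-profile dual-peak layer statistic (interepithelial MT intensity ratio),
    automated mitotic-event detection from paired pericentriolar-material
    foci with spindle confirmation, apical MT focus counting, an agent-based
    contact-loss-gated mitosis simulator with perturbation presets, a
    volumetric renderer with confocal optics, OME-TIFF input/output, and
    replicate-level summary statistics with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
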