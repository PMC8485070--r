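Package: sedenz
Title: Potential Extracellular Enzyme Activities and Enzyme Lifetimes in
    Subsurface Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fluorogenic extracellular enzyme assays in marine
    sediment slurries: matrix-matched standard-curve calibration, initial
    hydrolysis rate (v0) estimation with detection-limit flagging,
    Michaelis-Menten saturation-curve fitting, depth profiles of absolute
    and cell-specific potential activities with segmented cell-count
    interpolation, autoclave-retention statistics (Kruskal-Wallis omnibus
    and Conover-Iman pairwise rank tests), and a lower-bound model for
    extracellular enzyme turnover times with Monte-Carlo uncertainty
    propagation. Includes a synthetic-data generator with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
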