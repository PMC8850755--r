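Package: lipidflux
Title: Targeted Plasma Lipidomics Pipeline for Myocardial Reperfusion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a targeted (MRM) plasma lipidomics
    workflow for serial sampling around myocardial reperfusion: lipid
    shorthand parsing and panel handling, internal-standard semi-quantitation
    with acyl-chain correction factors and cholesteryl-ester response-factor
    lines, M+2 deisotoping, pooled-QC random-forest drift normalization with
    CoV and blank filtering, repeated-measures statistics with
    Greenhouse-Geisser correction and Bonferroni pairwise comparisons, and
    covariate-adjusted lipid-troponin association analyses. Includes a
    synthetic study generator emulating the acquisition design (batches, QC
    injections, injection-order drift, isotope interference) so the full
    pipeline is testable without access to the deposited study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
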