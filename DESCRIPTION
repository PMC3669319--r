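Package: cfba
Title: Constraint-Based Modeling of Cross-Feeding Microbial Communities at Balanced Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community flux balance analysis for microbial consortia growing in
    balanced growth, where every member species grows at the same specific rate
    and all intra- and extracellular metabolite pools are at steady state.
    Given per-species stoichiometric models (a plain tabular dialect or a
    subset of SBML Level 3 with flux bounds), the package assembles the merged
    community stoichiometric matrix, solves the fixed-fraction linear program
    for the community growth rate, scans the biomass-fraction simplex for the
    globally optimal species composition, and provides higher-order analyses:
    flux-bound phase planes with limitation-regime classification,
    dual-limitation detection, flux-variability ranges at the community
    optimum, and a one-at-a-time cross-feeding-metabolite screen at a fixed
    (chemostat) growth rate. Results are tibbles throughout, with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
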