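Package: metstab
Title: Yield Stability Analysis for Multi-Environment Crop Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-environment variety trials: combined
    randomized-complete-block ANOVA with sum-of-squares partitioning,
    the additive main effects and multiplicative interaction (AMMI)
    model with interaction principal component (IPCA) scores, the AMMI
    stability value (ASV) and genotype selection index (GSI), and GGE
    biplot geometry including environment discrimination and
    representativeness diagnostics and the which-won-where convex-hull
    sector partition. Ships the cell-mean yield matrix of a 12-variety,
    9-location irrigated lowland bread wheat trial (Oromia, 2021) as a
    worked example, and a seeded generator of replicated trial data
    with a known low-rank genotype-by-environment interaction for
    validating every stage against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    grid,
    grDevices,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
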