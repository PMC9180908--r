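Package: hydrorisk
Title: Groundwater Quality Indices, Health-Risk Assessment and Source
    Apportionment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for stratified groundwater hydrochemistry studies:
    charge-balance quality control in milliequivalents, descriptive
    statistics and guideline exceedance against WHO-style limits,
    hydrogeochemical facies classification (Gibbs ratio plots and the
    Chadha coordinate scheme), single-parameter Nemerow pollution
    indices and aggregate pollution indices, USEPA-style human health
    risk assessment (chronic daily intake, hazard quotients, cancer
    risks and total hazard indices per exposure cohort), varimax-rotated
    principal component analysis with an R-squared-difference
    multilinear-regression source-contribution procedure, Ward
    hierarchical clustering, and a seeded synthetic sample generator
    emulating the stratified multi-source structure of field campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
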