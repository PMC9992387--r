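Package: osteokit
Title: Quantitative Zooarchaeology: Skeletal-Part Quantification, Diet
    Breadth, Taphonomy, Transport-Attrition Inference and Site Catchments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of archaeofaunal
    assemblages: specimen-level record handling with controlled
    vocabularies, quantification indices (NISP, MNE from anatomical
    portion codes, MNI, MAU and percent MAU), diet-breadth and
    prey-selection statistics (inverse Simpson index, juvenile/adult
    ratios, habitat and rank ratios, biomass, ternary mortality
    coordinates), taphonomic summaries of butchery, burning and
    diagenetic modifications, Bayesian inference of carcass-transport
    preference and density-mediated attrition from skeletal-part
    profiles via Markov chain Monte Carlo, anisotropic travel-time site
    catchments on digital elevation models with slope-based habitat
    partitioning, net-primary-productivity statistics and
    productivity-diversity correlation, and a synthetic assemblage
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
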