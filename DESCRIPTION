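Package: podnet
Title: Boolean Modeling of the Arabidopsis Fruit Dehiscence-Zone Gene Regulatory Network
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synchronous Boolean network analysis of the gene regulatory network
    that patterns the medio-lateral axis of the Arabidopsis fruit into valve,
    lignification layer, separation layer and replum. Ships two curated rule
    sets (a literature-compiled network and an extended network adding the NTT
    transcription factor with hypothetical interactions), exhaustive attractor
    and basin enumeration, in-silico loss- and gain-of-function mutant
    simulation, robustness analysis against topology-matched random network
    ensembles (function bit-flip and state-transition perturbations),
    conversion of Boolean models to continuous (fuzzy-logic/sigmoid) dynamical
    systems to resolve artifactual cyclic attractors, and a constraint-based
    Boolean rule search over signed, annotated topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    deSolve,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
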