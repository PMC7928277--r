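Package: ethnomineR
Title: Association Mining and Citation Statistics for Ethnobotanical
    Prescription Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of ethnobotanical prescription surveys:
    relative frequency of citation (RFC) statistics with a frequent-material
    filter, categorical profiling of medicinal materials (taxonomy, part
    used, thermal property, flavor, pharmacology tags) under explicit
    counting conventions, support-thresholded drug-pair mining,
    confidence-based association rules, and co-prescription network
    inference with core-material ranking. Includes a seeded synthetic
    prescription-corpus generator (independent Bernoulli inclusion,
    deterministic implications, mixture-coupled pair boosts) so every stage
    is testable without restricted survey data, and a one-command pipeline
    that writes tables, a GraphML network, a Markdown report, and a
    reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'corpus-io.R'
    'ethno-indices.R'
    'association-mining.R'
    'synthetic-data.R'
    'pipeline.R'
    'ethnomineR-package.R'
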