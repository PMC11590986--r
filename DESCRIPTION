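Package: caseolapr
Title: CaseOLAP Text-Cube Mining and Knowledge-Graph Analysis of
    MeSH-Indexed Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline linking calcium-regulating proteins,
    oxidative-stress (OS) molecules, and eight cardiovascular-disease (CVD)
    categories through literature mining. Builds MeSH-defined text cubes from
    a document corpus, detects protein mentions with a curated dictionary,
    computes CaseOLAP popularity/distinctiveness/combined scores per
    (protein, category), assembles a heterogeneous knowledge graph (protein,
    document, MeSH, pathway nodes), scores OS molecules and pathways by
    co-occurrence, ranks candidate protein-MeSH links with common-neighbour
    topology measures, and analyses the score matrix with PCA and
    hierarchical clustering. A synthetic-corpus generator with planted
    (protein, category) associations supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
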