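Package: modelgraph
Title: Property-Graph Storage and Retrieval for Systems-Biology Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An embedded property graph for computational-biology model
    repositories. Imports SBML, CellML and SED-ML documents and
    bio-ontologies (SBO, GO, KiSAO) into a single labelled graph,
    materialises explicit links between annotations and ontology
    concepts, between simulation descriptions and stored models, and
    between observed variables and model entities, and infers implicit
    cross-format entity correspondences from shared reference
    publications and name similarity. A pattern-matching and
    aggregation layer together with a TF-IDF full-text index over
    annotation descriptions answers structural, statistical and ranked
    retrieval queries across all stored data domains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
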