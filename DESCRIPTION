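Package: mosqnet
Title: Bipartite Network Analysis of Mosquito Vector-Pathogen Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the global bipartite network of mosquito
    vectors and the human pathogens they carry. Literature evidence records
    (wild infection, laboratory infection, dissemination, transmission,
    known-vector status) are collapsed into a 1-5 evidence score per
    vector-pathogen pair; scored pairs form a weighted two-mode network.
    The package computes nestedness (NODF), Newman-Girvan modularity,
    Louvain communities and normalized betweenness centrality from first
    principles, simulates secondary pathogen extinction under random or
    targeted vector removal (extinction curves, area-under-curve
    robustness, break points), classifies pathogens by certainty versus
    scale of the vector problem, and generates synthetic evidence tables
    with planted community structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'betweenness.R'
    'evidence.R'
    'extinction.R'
    'louvain.R'
    'modularity.R'
    'mosqnet-package.R'
    'network.R'
    'nodf.R'
    'pipeline.R'
    'profiling.R'
    'synthetic.R'
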