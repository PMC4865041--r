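Package: goDiseaseNet
Title: GO-Disease Inference Networks, Disease Similarity and Drug
    Repositioning from Curated Annotations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds transitive GO-disease inference networks by joining
    direct GO-gene annotations (gene2go dialect) with curated gene-disease
    associations (CTD dialect), subsumes inferences over the GO DAG and a
    MEDIC-style disease hierarchy, ranks disease pairs by Jaccard similarity
    of shared inferred GO biological-process terms under disjoint-gene and
    gene-count-parity filters, tests overlap significance (hypergeometric,
    Pearson chi-square, Bonferroni), and prioritises drug-repositioning
    candidates by coverage of a reference gene set. Includes a seeded
    synthetic-data generator that emits every input dialect together with a
    ground-truth ledger, including planted disease pairs that share GO
    processes through disjoint gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
biocViews: Software, Annotation, GO, Network, GraphAndNetwork
RoxygenNote: 7.3.3
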