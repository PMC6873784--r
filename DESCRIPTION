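Package: ceRNAnet
Title: Competing Endogenous RNA Triplet Inference and Tripartite Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    "co-expression competing triplets" from case/control expression profiles of
    the three transcript classes: fold-change plus Student t-test differential
    expression filtering, miRNA seed-match target prediction and import of
    external prediction tables, Pearson-correlation pair selection with shared
    negatively co-expressed miRNAs, assembly of the tripartite network with
    centrality-based hub ranking (degree, betweenness, harmonic closeness,
    PageRank), random walk with restart node prioritisation, bidirectional
    hierarchical clustering into co-expression modules, and hypergeometric gene
    set enrichment. Includes a synthetic-data generator that plants recoverable
    triplets so the full pipeline can be benchmarked against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic.R'
    'io-expression.R'
    'io-network.R'
    'io-sequences.R'
    'diffexpr.R'
    'interactions.R'
    'cerna.R'
    'topology.R'
    'rwr.R'
    'modules.R'
    'pipeline.R'
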