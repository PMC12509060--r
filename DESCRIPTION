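Package: gxenet
Title: Genotype-by-Environment Effects on Gene Coexpression and Regulatory
    Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting genotype-by-environment (GxE) interactions
    in gene regulation from highly replicated RNA-seq designs with two
    genotypes and two environmental treatments. The package builds weighted
    gene coexpression networks and modules independently in each
    genotype-by-treatment library type, tests module-membership preservation
    across library types with an exact multi-set intersection test, infers
    directed regulatory interactions within modules by interventional greedy
    sparsest-permutation search with stability selection, tests genotype,
    environment and GxE effects on the slope and intercept of
    regulator-target regressions, and classifies cis/trans regulatory
    divergence from allele-specific expression in F1 hybrids and parents.
    A synthetic-data generator with planted modules, causal structure and
    allelic architectures provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ase.R'
    'ci.R'
    'cliques.R'
    'edge.R'
    'intersect.R'
    'io.R'
    'modules.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
    'stability.R'
    'tom.R'
    'utigsp.R'
    'utils.R'
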