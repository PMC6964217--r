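Package: pgnet
Title: Phenotype-Genotype Association Network Construction and Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bipartite phenotype-genotype networks from curated
    disease-ncRNA association tables and characterizes their topology.
    Fits discrete power laws to degree distributions by maximum likelihood
    with Kolmogorov-Smirnov goodness of fit and bootstrap confidence
    intervals, partitions miRNAs into universal (multi-disease) and
    specific (single-disease) classes, and contrasts the classes by
    biomarker enrichment (Fisher exact, chi-square and permutation tests),
    validated-target coverage and essential-gene ratios. Also assembles
    ternary sponge networks (lncRNA/circRNA-miRNA-mRNA), performs
    hypergeometric over-representation analysis against GMT gene-set
    collections with BH/Bonferroni adjustment, clusters miRNA
    tissue-expression profiles, and ships a synthetic-data generator that
    emulates the statistical structure of curated cardiovascular
    disease-ncRNA databases so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
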