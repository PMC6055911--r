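Package: tfgpmap
Title: Genotype-Phenotype Maps of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Maintainer", "tfgpmap", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds the genotype space of all 32,896 canonical double-stranded
    DNA 8-mers under a point-mutation plus shift-indel mutation model, derives
    per-transcription-factor genotype networks from protein binding microarray
    E-score tables, and computes intra- and internetwork statistics (clustering,
    assortativity, path lengths, route factor, overlap, mutational connectivity,
    phenotype accessibility, Bhattacharyya neighborhood similarity, phenotype
    space covering), size-preserving null-model ensembles, and in-vivo binding
    site diversity analyses (footprint filtering, site assignment, Shannon
    diversity, structure-diversity correlations). Includes a synthetic data
    generator emulating PBM, footprint and polymorphism inputs so the whole
    pipeline is testable offline.
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
    tools,
    methods,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
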