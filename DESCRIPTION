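Package: ProteoMetaAD
Title: Cross-Study Meta-Analysis of Protein Changes in Alzheimer's
    Disease Brain Tissue
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes differential-expression tables from published
    proteomic studies of human Alzheimer's disease brain tissue into a
    single corpus, scores each protein by vote counting across study
    comparisons, and classifies directional consistency with a
    one-outlier rule. Downstream modules compare protein changes between
    early-stage and advanced disease, between vulnerable and resistant
    brain regions, assign proteins to three temporal phases of disease,
    and call enrichment or depletion in microdissected neuropathological
    lesions (amyloid plaques, neurofibrillary tangles, cerebral amyloid
    angiopathy) together with their overlaps. A synthetic multi-study
    corpus generator with planted ground truth supports end-to-end
    recovery testing without access to the curated source data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: Proteomics, DifferentialExpression, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
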