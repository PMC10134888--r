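Package: mgInferEval
Title: Evaluating Metagenome Inference Accuracy in Vaginal Microbiome Studies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how faithfully marker-gene-based metagenome
    inference (e.g. PICRUSt2- or Tax4Fun2-style prediction of KEGG ortholog
    content from 16S rRNA profiles) reproduces shotgun-observed functional
    profiles, with the stratified evaluation design used in vaginal
    microbiome research: Jensen-Shannon divergence / Ward clustering into
    community state types, KO-specific Spearman concordance between observed
    and predicted relative abundances, concordance of signed log10
    Wilcoxon P values (case/control differential signal), permutation-null
    robustness checks, and linear-model coupling of functional-category
    abundance to dominant-taxon abundance. Includes a seeded synthetic
    generator of paired taxon/KO datasets with taxon-specific genome content
    and reference-fidelity error models, so the full evaluation pipeline is
    testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'community_structure.R'
    'composition_regression.R'
    'concordance_eval.R'
    'differential_eval.R'
    'io_tables.R'
    'mgInferEval-package.R'
    'synthetic_data.R'
    'pipeline.R'
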