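Package: ecmnet
Title: Extracellular Matrix Network Analysis for Soft-Tissue Sarcoma Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for extracellular-matrix (matrisome) and
    integrin-adhesome profiling of tumour proteomes. Provides annotation
    filtering against matrisome/adhesome catalogs, coregulated-network
    discovery by consensus clustering of protein-protein correlations with
    PAC model selection and SigClust significance testing, single-sample
    gene-set enrichment (ssGSEA) and hypergeometric overrepresentation
    analysis, SAM permutation differential analysis, gene-set prognostic
    scoring with log-rank/Cox screening, cell-migration track metrics
    (speed, directionality index), immunohistochemistry scoring (H-score,
    positive-pixel fraction, TIL densities, mixture clustering), and a
    synthetic-cohort generator with block-correlated expression programs
    and program-linked survival for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
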