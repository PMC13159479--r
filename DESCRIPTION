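Package: pestewas
Title: Epigenome-Wide Association Pipeline for Ambient Pesticide Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline linking ambient agricultural
    pesticide exposure to genome-wide DNA methylation. Covers buffer-based
    exposure scoring from pesticide-use records and address histories,
    methylation probe filtering and per-feature winsorization,
    covariate-adjusted residualization, probe-level association by biweight
    midcorrelation and moderated-t regression, genomic inflation estimation
    with empirical-null correction, bump-hunting detection of differentially
    methylated regions with permutation p-values, and CpG-count-bias-corrected
    gene-set overrepresentation. Ships a synthetic-data generator with known
    ground truth so every stage can be validated by parameter-recovery and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
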