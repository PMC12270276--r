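Package: gutbrainlink
Title: Multistage Microbiota-Gut-Brain Linkage Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of a multistage
    microbiota-gut-brain linkage pipeline: untargeted-metabolomics quality
    control and normalization (QC/blank ratio, RSD, presence filtering,
    minimum-value imputation, generalized-log transform, z-scoring),
    first-component partial least squares regression linking a genus-level
    microbial abundance to the fecal metabolome with a permutation null and
    loading-based metabolite selection, resting-state fMRI metrics (ALFF,
    fALFF, ReHo, FCD, VMHC) with whole-brain-mean standardization and
    cluster-mean extraction, covariate-adjusted partial Spearman correlation
    screens with Benjamini-Hochberg false discovery rate control,
    regression-based single-mediator analysis with bootstrap percentile
    confidence intervals, hypergeometric pathway over-representation of the
    selected metabolite sets, and a synthetic-cohort generator that plants
    every effect the pipeline is designed to detect, so that the whole chain
    is testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
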