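Package: methylarow
Title: Cell-Type Classification of DNA Methylation Profiles with AROW
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminates human pluripotent stem cell types (embryonic stem
    cells, induced pluripotent stem cells, embryonal carcinoma cells and
    somatic cells) from Illumina methylation-array beta values using an
    Adaptive Regularization of Weight vectors (AROW) online linear
    classifier trained one-vs-others. Provides GenomeStudio-style beta
    matrix input/output with probe quality filtering, a 4-fold
    cross-validation protocol with a regularization sweep and epoch
    checkpointing, macro-averaged evaluation metrics, mining of the learned
    determination weights into a cross-fold epigenetic signature,
    subsample-resampling variability statistics for differentially and
    variably methylated CpG sites, and a synthetic cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
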