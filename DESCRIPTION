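Package: adaptnipt
Title: Adaptive Reference-Sample Selection for cfDNA Aneuploidy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth based screening for fetal trisomies 13, 18 and 21 from
    shallow-sequenced maternal plasma cell-free DNA. Implements GC-bias
    correction of binned read counts by locally weighted regression,
    per-chromosome reads fractions, cross-sample normalization against a
    euploid reference panel, linear regression of reads fraction on GC
    content with residual z-scores, and an adaptive reference-selection
    algorithm that, for every test sample, extracts the GC/reads-fraction
    matched panel subset by stepped window expansion and coefficient-of-
    variation minimization. Includes a synthetic-cohort generator with
    sample-specific GC-bias curves for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
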