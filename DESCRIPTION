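Package: netdax
Title: Individualized Dual-Axis Network Topology for Focal Epilepsy Connectomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates reliable overlapping resting-state functional networks at the
    single-subject level by block-bootstrap sparse dictionary decomposition, and derives
    two complementary topological axes from them: system integrity (Dice correspondence
    of individualized networks to canonical atlases, summarized as canonical network
    representation, normativity and non-normativity, with spin-permutation inference and
    cross-atlas consensus parcel maps) and system integration (voxel-wise k-hubness, the
    number of overlapping networks a voxel participates in, aggregated over gray-matter
    regions). Downstream stages convert metrics into covariate-adjusted normative
    deviation scores (w-scores) via Bayesian spline regression with optional
    heteroskedastic noise, test group deviations with BH-FDR and max-T sign-flip
    permutation corrections, infer disease subtypes and stages with a z-score event-based
    model, and link topology deviations to clinical-cognitive blocks via sparse canonical
    correlation with permutation-based penalty selection. A synthetic-data module
    generates every input with recorded ground truth, so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    RNifti,
    splines,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
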