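Package: mrsq
Title: Tissue- and Relaxation-Corrected Quantification for Single-Voxel MRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Water-referenced quantification of brain magnetic resonance
    spectroscopy (MRS) with partial-volume and relaxation correction, and
    tools to quantify how differences between anatomical segmentation
    methods propagate into molar metabolite concentration estimates.
    Extracts gray-matter, white-matter and CSF fractions within an MRS
    voxel from tissue-probability maps, applies the water-referenced
    tissue-and-relaxation correction, fits the balanced repeated-measures
    Method-by-Session model with participant random intercepts, and
    provides percent-difference summaries, age-association tests with
    Steiger's Z for dependent correlations, and a synthetic test-retest
    study generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    emmeans,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
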