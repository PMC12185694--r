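Package: neurofluidr
Title: Neurofluid MRI Analysis: BOLD-CSF Coupling, Glymphatic Kinetics,
    Pulsation Power and ASL Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative neurofluid MRI analysis: cross-correlation
    coupling between cortical BOLD and ventricular CSF inflow signals,
    tracer-kinetic parameter extraction (arrival time, time-to-peak, influx
    rate, exponential decay) from dynamic gadolinium-enhanced glymphatic MRI,
    cardiac-band arterial pulsation power with explicit frequency-alias
    handling, and cerebral blood flow quantification from pseudo-continuous
    arterial spin labeling. Includes frame-wise-displacement motion scrubbing,
    a normality-gated statistical toolkit with Holm-Bonferroni correction,
    partial correlation and permutation-based voxel-wise cluster inference,
    and a synthetic-data module that generates all inputs with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
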