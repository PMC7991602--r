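Package: hydroquant
Title: Volumetric Quantification of Endolymphatic Hydrops from Inner-Ear MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies endolymphatic hydrops (EH) from delayed
    gadolinium-enhanced inner-ear MRI. Builds HYDROPS and HYDROPS-Mi2
    contrast images from MR cisternography (MRC) and positive
    perilymph/endolymph FLAIR images (PPI/PEI), segments the total fluid
    space with a phantom-derived probabilistic atlas and in-ROI
    thresholding, classifies the endolymphatic space with a volumetric
    local thresholding (VOLT) ensemble (Niblack and local-mean thresholds
    at two window scales along three orthogonal orientations, vote
    cut-off), derives semi-quantitative hydrops grades and volumetric
    asymmetry measures, computes neurotologic asymmetry ratios (Jongkees
    caloric formula, VEMP amplitude ratios) and deficit classifications,
    and reproduces the cohort association statistics (chi-square with phi,
    r x c Fisher exact, Spearman, ANOVA with Bonferroni correction). A
    parametric two-compartment labyrinth phantom generator provides ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
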