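Package: glymph
Title: Glymphatic MRI Markers: DTI-ALPS, Perivascular Markers, and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the diffusion-tensor image analysis along the
    perivascular space (DTI-ALPS) index from diffusivity volumes with a
    five-position region-of-interest shift battery, derives cerebral
    small-vessel-disease, amyloid and glymphatic markers (log white matter
    hyperintensity burden, normalized choroid plexus volume, perivascular
    space visual grades, amyloid positivity, AD-continuum group assignment
    and quality-control exclusions), and runs the associated statistical
    chain: W-score normative deviations against a reference group,
    covariate-adjusted partial correlations, cumulative-link ordinal models
    for perivascular space grades, Benjamini-Hochberg false discovery rate
    control, continuum curve fitting, and bootstrap product-of-coefficients
    mediation. Includes a synthetic-data module (tensor phantoms with known
    ground-truth ALPS and a linear structural-equation cohort generator) so
    the full pipeline is testable without access to cohort imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    graphics,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
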