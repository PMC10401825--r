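Package: lungstrain
Title: Dynamic Lung CT Aeration, Volumetric Strain and Tidal Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of paired end-expiratory and end-inspiratory
    lung CT volumes from mechanically ventilated subjects. Converts Hounsfield
    units to voxel gas fractions, classifies aeration compartments and their
    mass fractions, estimates the end-expiratory to end-inspiratory deformation
    with a multiresolution B-spline-regularized diffeomorphic registration,
    derives voxel-level volumetric strain from the Jacobian determinant,
    quantifies tidal recruitment and vertical (gravitational) distributions in
    iso-gravitational regions of interest, builds strain-colored parametric
    response maps, fits single-compartment respiratory mechanics for
    decremental PEEP trials, and generates synthetic deformable lung phantoms
    with closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
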