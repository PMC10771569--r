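Package: ireplan
Title: Treatment Planning for Irreversible Electroporation in Tumor-Mimicking Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational planning of multi-electrode irreversible
    electroporation (IRE) in liver-tumor-mimicking hydrogel phantoms.
    Solves the quasi-static conduction problem div(sigma grad phi) = 0 on
    regular 2D and 3D grids with Dirichlet needle-electrode boundary
    conditions and field-dependent tissue conductivity, superposes
    sequentially activated electrode pairs into a cumulative exposure
    field, maps candidate electric-field thresholds to ablated areas and
    volumes, inverts measured ablation back to a per-sample IRE field
    threshold with mean and standard deviation, and classifies tumor
    coverage against experimental and literature thresholds. A synthetic
    data module generates noisy ablation measurements, bumpy-ellipsoid
    tumor masks, inter-electrode resistance readouts, and binary
    live/dead z-stacks so the full pipeline runs without wet-lab inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
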