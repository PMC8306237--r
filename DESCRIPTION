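Package: ivimhsi
Title: Hyperspectral Target Detection and IVIM Quantification for
    Multi-b-Value Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Treats a multi-b-value intravoxel incoherent motion (IVIM)
    diffusion-weighted MR slice as a hyperspectral image cube (one band per
    b-value) and detects breast lesions without supervision using the
    constrained energy minimization (CEM) family of subpixel detectors
    (iterative CEM and kernel CEM with ATGP/SAM target seeding and a band
    expansion process) as well as K-means and fuzzy C-means clustering.
    Detected lesions are quantified by bi-exponential IVIM fitting (ADC,
    signal decay slope, D, D*, perfusion fraction) and segmentations are
    scored with Dice, Jaccard and confusion-matrix rates. Includes a
    digital phantom generator with known lesion masks and tissue
    parameters so the whole chain is testable end to end, plus simplified
    preprocessing (polynomial bias-field correction, integer-translation
    band registration, breast-region extraction) and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
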