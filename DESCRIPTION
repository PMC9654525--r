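Package: dualstain
Title: IHC-Supervised Annotation and Tumor Burden Estimation for Digital H&E/IHC Dual Stains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for immunohistochemistry (IHC)-supervised annotation of
    H&E-stained tissue from registered dual stains of the same section.
    Includes a synthetic dual-stain scene simulator with exact ground truth
    (chromogen-positive tumor nuclei, hematoxylin-stained normal nuclei,
    melanin pigment, unspecific red dots, cytoplasmic reactions, misalignment),
    stain color arithmetic (chromaticity, optical density, color
    deconvolution for H&E+DAB and H&E+Fast-Red), chromaticity/deconvolution
    threshold annotators, phase-correlation registration with categorical
    label transfer, morphological postprocessing with watershed cluster
    splitting, a compact U-net for nucleus classification (3-band or 6-band
    input), tumor-burden quantification with systematic-random sampling and
    the stereological unbiased counting frame, and validation statistics
    (precision with Wilson score intervals, two-sample proportion tests,
    pixel confusion-matrix metrics, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
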