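Package: spermshape
Title: Fourier Harmonic Shape Analysis of Sperm Nuclei and Fertility
    Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify sperm nuclear morphology from fluorescence
    microscopy and relate it to male fertility. Includes a synthetic image
    generator with known ground truth, Laplacian-of-Gaussian nucleus
    segmentation with perimeter tracing, ImageJ-style morphometric and
    intensity measurements, Fourier harmonic amplitude (FHA) shape
    descriptors obtained by trigonometric regression of polar radius
    profiles, and a two-group linear discriminant fertility classifier with
    stepwise Wilks-lambda variable selection and leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
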