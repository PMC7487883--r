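Package: ihcloc
Title: Protein Subcellular Localization and Translocation Biomarker
    Detection from Immunohistochemistry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for brightfield immunohistochemistry
    (IHC) of tissue sections. Separates hematoxylin (DNA) and diaminobenzidine
    (protein) stains by fixed-basis linear spectral unmixing or per-image
    blind non-negative matrix factorization, selects high-expression square
    interest patches, computes an 848-dimensional engineered feature vector
    per patch (DNA colocalization/distance features, Haralick texture on
    Daubechies wavelet subbands, local binary patterns), augments it with
    penultimate-layer features of convolutional backbones including a
    GapNet-style SELU network, reduces dimensionality by stepwise
    discriminant analysis, classifies nuclear / cytoplasmic-membranous /
    mixed localization with RBF-kernel support vector machines under
    per-image or per-protein cross-validation, and screens proteins for
    cancer-associated subcellular translocation with per-dimension
    independent two-sample t-tests on classifier score vectors. A synthetic
    image generator with Beer-Lambert stain mixing provides ground-truthed
    data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
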