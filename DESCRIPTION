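Package: otsufuse
Title: Seedling Emergence Mapping by Otsu-Intersection Fusion of Vegetation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates crop seedling emergence rate from co-registered
    visible (RGB digital-number) and five-band multispectral reflectance
    rasters of mulched cotton fields. Computes a bank of 39 spectral
    layers (raw channels plus visible and multispectral vegetation
    indices), binarizes each with Otsu's method, fuses the best
    separating indices by pixelwise intersection (OI) or by pixel-level
    machine-learning classification (SVM, random forest, k-nearest
    neighbours), cleans the fused mask morphologically, counts seedlings
    per square grid cell by connected-component labeling, and converts
    counts to emergence-rate percentages. A ground-truthed synthetic
    field-scene simulator (plastic mulch film, drip tape, bare soil,
    seedling canopies) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    randomForest,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
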