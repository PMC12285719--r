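Package: plumoptics
Title: Multilayer Optical Modelling and Avian Visual Analysis of Plumage Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how hidden white and black feather layers modulate plumage
    color. Implements a three-layer optical model of feather stacks (colorful,
    achromatic, downy) with per-layer reflectance/transmission/absorption
    spectra, spectral colorimetry (brightness, saturation, hue), tetrachromat
    receptor-noise visual modelling (quantum catches, tetrahedral color space,
    chromatic and luminance just-noticeable differences), HSL image
    segmentation and hyperspectral region-of-interest sampling, together with
    seeded synthetic-data generators and pipeline drivers for background-swap,
    parameter-sweep and dichromatism experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    pracma,
    yaml,
    jsonlite,
    png,
    tiff
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
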