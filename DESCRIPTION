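Package: specqtl
Title: Multispectral Leaf-Color Phenotyping and Pseudo-Testcross QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping plant color and cover from nine-band
    multispectral images (NIR-based segmentation, per-band median spectra,
    sum-to-one spectral standardization, fifteen vegetation indices, and
    principal component analysis of the standardized spectra) and for mapping
    the genetic basis of those traits in an outbred F1 population by the
    pseudo-testcross strategy: parent-specific two-point linkage maps,
    Haley-Knott regression and composite interval mapping on a pseudomarker
    grid, permutation significance thresholds, and QTL-genotype class
    comparisons. Includes a synthetic-data module that generates multispectral
    scenes with ground-truth masks and simulated F1 crosses with planted QTLs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    png,
    jsonlite
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
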