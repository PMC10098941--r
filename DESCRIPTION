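Package: wtm
Title: Weibull Tone Mapping for Underwater Image Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tone-mapping toolkit for artificially lit seafloor imagery.
    Brightness histograms are represented by best-fit Weibull proxy
    distributions (fitted by exhaustive Kullback-Leibler grid search), and
    tone curves are built that map one Weibull proxy onto another, so an
    image can be enhanced with two intuitive parameters: scale lambda
    (brightness) and shape k (contrast). Includes histogram equalisation
    and contrast-limited histogram equalisation baselines, monotone
    control-point (PCHIP) tone curves, approximation of arbitrary tone
    adjustments by their closest Weibull tone map, CIELAB mean Delta E
    evaluation, observer-session agreement statistics, and seeded
    generators for synthetic seafloor scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    jpeg,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
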