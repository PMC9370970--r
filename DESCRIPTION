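Package: tubershape
Title: Ellipse-Fitting Shape Irregularity Scoring for Tuber Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Machine-vision grading of tuber (potato) shape from single-object
    images on a dark background. A capture is downscaled by region (area)
    interpolation, grayed, segmented with Otsu's threshold, cleaned with
    morphological and majority filtering, and centered; the object contour is
    traced and fitted to an ellipse by direct least squares. Four
    contour-versus-ellipse similarity features -- perimeter ratio, area ratio,
    bidirectional Hausdorff distance, and intersection-over-union of the
    filled regions -- score shape irregularity, and fixed thresholds classify
    each tuber as regular or irregular, with optional multi-view aggregation.
    Includes confusion-matrix evaluation metrics, a seeded synthetic generator
    of labeled tuber-like images for end-to-end validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    tiff,
    jpeg
Config/testthat/edition: 3
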