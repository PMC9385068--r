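Package: ldpstream
Title: Local Differential Privacy for Wearable-Device Data Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Privacy-preserving collection of single-attribute numerical
    stream data (e.g. minute-resolution heart rate from wearable devices)
    under local differential privacy. Device-side salient-point extraction
    compresses each stream to its shape-defining points, an adaptive
    Laplace mechanism perturbs the retained values under a per-point
    privacy budget, and the collector reconstructs each curve on the full
    timestamp grid (linear, shape-preserving cubic Hermite, or not-a-knot
    cubic spline) before estimating per-timestamp means across devices.
    Includes Laplace-mechanism comparison baselines, a seedable synthetic
    heart-rate stream generator, and an evaluation harness reporting mean
    relative error and root-mean-square error of the estimated mean curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
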