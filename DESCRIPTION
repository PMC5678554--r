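Package: pymleaf
Title: Projected Leaf Area from Blue-Filtered NIR Imaging and Rosette
    Growth Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments rosette plants from (VIS+NIR) blue-filtered images by
    spectral channel subtraction (NEW CHANNEL = RED - k*BLUE), Otsu
    thresholding and morphological cleanup, and converts the segmented
    foreground into calibrated projected leaf area. Downstream analytics
    turn per-plant area time series into thermal time, relative expansion
    rates, neighbour-overlap-corrected areas, intercepted radiation, and
    radiation interception and use efficiencies, including an exponential
    expansion-rate model with likelihood-ratio treatment comparison. A
    synthetic scene and trajectory generator provides ground-truthed
    fixtures so every stage is testable without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
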