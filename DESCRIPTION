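Package: gutmotion
Title: Spatiotemporal Analysis of In Vitro Intestinal Motility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for calibrated diameter matrices (kymographs /
    spatiotemporal maps) of isolated intestinal preparations. Computes the
    bulbous emptying time of the dilated anterior segment from a
    quantile-threshold rule on its average width, selects standardized 30-min
    analysis sub-periods around the emptying time, detects contraction events
    as connected constriction regions, classifies them as standing, ripple or
    slow propulsive contractions from propagation distance and the linearity
    of the constriction path, and summarizes frequency, amplitude, duration,
    distance, velocity and propagation direction per intestinal segment and
    digestive period. A calibrated synthetic-scenario generator with full
    ground truth stands in for raw video recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
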