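Package: sdmax
Title: Maximum-Entropy Species Distribution Modelling with AICc Model
    Selection and Climate-Change Range Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence/background habitat-suitability modelling on gridded
    environmental layers: linear/quadratic/product/threshold/hinge feature
    expansion, an L1-regularized maximum-entropy (Gibbs) model fitted by
    proximal gradient descent, cloglog suitability output, AUC and
    small-sample AICc evaluation, candidate-model selection over a
    regularization-multiplier by feature-class grid, collinearity-aware
    variable selection, max(sensitivity+specificity) thresholding into
    four suitability classes, spherical class-area accounting, and
    climate-scenario change analytics (stable/expand/shrink overlays,
    class-transition matrices, and centroid trajectories of the most
    suitable habitat). Includes a synthetic-data module that generates
    correlated smooth random environmental fields with a known true niche
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
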