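Package: cayolo
Title: Context-Aware Single-Stage Detection of Clue Cells in Fluorescence Microscopy Images
Version: 0.1.0
Authors@R: person("cayolo", "maintainers", email = "cayolo@example.org", role = c("aut", "cre"))
Description: A single-stage object detector for screening bacterial vaginosis
    slides: clue cells (Gardnerella-coated epithelial cells) are told apart
    from normal epithelial cells by edge granularity and surface punctae
    rather than size or shape. The package provides a context-aware module
    (CAM) and a shuffle global attention mechanism (SGAM) as drop-in feature
    map transforms, a focal-loss-enhanced detection objective for severe
    class imbalance, a compact YOLO-style backbone/neck/decoupled-head
    assembly hosting the blocks, a synthetic fluorescence-scene generator
    with YOLO-format annotations, screening-style image-level and
    object-level evaluation, and paired statistical comparison of detectors
    (McNemar's test, bootstrap confidence intervals). Training runs on a
    small reverse-mode autograd with compiled im2col convolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
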