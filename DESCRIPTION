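Package: bunet
Title: Bayesian U-Net with Active Learning for Semantic Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains pixel-wise semantic segmentation networks from a minimal
    number of labelled images. Implements a U-shaped encoder-decoder
    convolutional network whose Bayesian treatment comes from max-pool
    dropout and batch normalization, Monte-Carlo dropout inference that
    averages T stochastic forward passes, four image-level acquisition
    functions (maximum entropy, BALD, committee Kullback-Leibler and
    committee Jensen-Shannon divergence), and the pool-based active-learning
    loop that queries a simulated oracle for the most informative images and
    warm-start retrains with early stopping on the validation dice
    coefficient. Ships a synthetic multi-class shape-segmentation generator
    and affine augmentation so the whole pipeline is testable on a desktop
    CPU.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
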