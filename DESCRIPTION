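Package: contrawr
Title: Self-Supervised Contrastive Representation Learning for
    Multichannel Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Learns vector representations of fixed-length multichannel
    physiological signal epochs (such as 30-second sleep-EEG windows)
    without labels, by contrasting two augmented views of each epoch
    against the batch-average "world representation" under a
    Gaussian-kernel triplet loss, with an exponential-moving-average
    target network.  Includes signal augmentations (zero-phase Butterworth
    bandpass, band-limited noising, channel flipping, circular shifting),
    a short-time-Fourier-transform convolutional encoder with a
    unit-hypersphere projection head, an instance-aware (softmax-weighted)
    world representation, a top-X nearest-neighbour negative baseline, a
    frozen-encoder logistic linear probe and a supervised reference model,
    a label-fraction sweep protocol, and a synthetic sleep-EEG generator
    so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
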