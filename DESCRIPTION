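Package: woacnn
Title: Whale-Optimization-Trained Convolutional Networks for Skin Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains small convolutional neural networks for two-class
    dermoscopy image classification with the whale optimization algorithm
    (WOA), a population metaheuristic modelled on humpback-whale bubble-net
    hunting, as an alternative to backpropagation.  Provides the WOA as a
    general continuous minimizer, a from-scratch CNN (forward pass,
    softmax/cross-entropy and MSE losses, gradient-descent training with an
    analytic-gradient backward pass), direct weight-and-bias optimization and
    integer hyperparameter search, sliding-window lesion mask prediction,
    sensitivity/specificity/PPV/NPV/accuracy reporting, and a seeded
    synthetic dermoscopy image generator so the whole pipeline is testable
    without external image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
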