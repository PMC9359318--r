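Package: vdpnet
Title: Variational Density Propagation Networks with Predictive-Variance
    Failure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian convolutional classifiers by variational density
    propagation (VDP): the mean and covariance of a Gaussian variational
    posterior over the weights are propagated analytically through every
    layer (convolution, nonlinearity, max-pooling, flattening, fully
    connected, softmax, batch normalization, residual connections), so the
    network outputs a predictive distribution without test-time sampling.
    Includes the evidence-lower-bound training objective, a deterministic
    twin for calibration comparisons, Gaussian and speckle noise corruption
    at target signal-to-noise ratios, FGSM and PGD adversarial attacks, and
    two predictive-variance failure-detection mechanisms (fixed and learned
    per-image variance thresholds) with abstention reporting. A synthetic
    multi-class image generator makes the full pipeline reproducible
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
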