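Package: qconv
Title: Quadratic Convolutional Models of Neural Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits position-invariant multi-feature receptive-field models
    ("quadratic convolutional" models) to stimulus movies and spike counts by
    Poisson maximum likelihood with stochastic gradient descent and four-fold
    early-stopping ensembles.  Significant excitatory and suppressive stimulus
    features are extracted from the quadratic kernel by a shuffle-null
    eigenvalue test, decomposed into Gabor wavelets (or quadrature pairs) by
    self-adaptive rand/2/bin differential evolution, and summarized with
    population metrics: lifetime sparseness with and without suppression,
    axial orientation spread, excitatory-suppressive orientation differences,
    pooling-mask decomposition, and Hartigan's dip test.  Includes synthetic
    ground-truth model neurons and stimulus generators for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    generics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
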