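Package: cfaug
Title: Adversarial Counterfactual Augmentation for Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for improving a binary image classifier with a frozen
    conditional counterfactual generator by playing an adversarial game on
    the generator's conditional factor.  Target ages are pushed by gradient
    ascent toward maximal classifier loss, the resulting hard counterfactuals
    are added to training, and the classifier is retrained; variants cover a
    continual-learning memory buffer and recovery from spurious
    age-diagnosis correlations.  Includes a differentiable Fourier feature
    encoder for conditional factors, a differentiable synthetic ageing-brain
    simulator that serves as dataset source and oracle generator, reference
    classifier and generator implementations, baseline augmentation
    strategies, and group-stratified evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
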