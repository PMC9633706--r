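Package: koagan
Title: Synthetic Knee Osteoarthritis Radiographs via Wasserstein GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for generating and auditing synthetic (DeepFake) knee
    osteoarthritis radiographs. Provides a synthetic phantom radiograph
    generator for end-to-end testing, X-ray preprocessing (histogram
    equalization, orientation normalization, negative-image inversion,
    Laplacian-variance focus filtering), Wasserstein GAN training with
    gradient penalty on a published generator/critic architecture, Frechet
    Inception Distance model selection, nearest-neighbor memorization
    auditing, survey-response scoring with balanced accuracy, latent-space
    exploration, and an augmentation/anonymization dataset-construction
    experiment with a transfer-learning classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
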