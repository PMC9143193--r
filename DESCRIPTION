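Package: hazegan
Title: Attention-Guided Adversarial Removal of Haze-Spot Noise from
    Infrared Livestock Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrared cameras on livestock farms accumulate insect
    secretions on the lens that reflect the camera's own IR emitters and
    form bright localized "haze spots", degrading downstream animal
    detection. hazegan simulates this noise with the atmospheric
    scattering model (uniform, linear and exponential spot profiles),
    generates paired clean/noisy training data from a built-in synthetic
    infrared scene generator, and trains a multi-scale spatial-attention
    U-Net generator against a conditional discriminator with a four-term
    objective (adversarial, L1 content, perceptual and multi-level
    attention losses). Image quality (MSE/PSNR) and detection quality
    (precision, recall, average precision at IoU 0.5) evaluators are
    included. All networks, back-propagation and the Adam optimizer are
    implemented in R with RcppArmadillo convolutions, so the full
    pipeline runs on a single CPU with no external framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
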