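Package: qusmigrate
Title: Cross-Scanner Migration of Quantitative Ultrasound Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for migrating a quantitative ultrasound (QUS) tissue
    classifier from one scanner (the victim machine) to another (the
    perpetrator machine) when the original model is reachable only through
    an input-output score interface. Implements depth-gated Wiener transfer
    function calibration between machines from paired calibration-phantom
    views, percentile pseudo-labeling through the opaque interface,
    iterative learning with noisy labels using small-loss anchors, and
    final retraining in the perpetrator's native data domain. Ships a
    point-scatterer radio-frequency (RF) speckle simulator with
    machine-specific pulse spectra and class-specific phantom attenuation,
    so the full pipeline is exercisable without access to scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Rcpp, signal, stats, graphics, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, pROC, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
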