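Package: schnetr
Title: Pathological Speech Detection with the Sch-Net Convolutional Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end detection of pathological (schizophrenic) speech from
    audio recordings. Implements the Sch-net convolutional neural network
    (a VGG-style backbone with three average-pooled skip connections, a
    convolutional block attention module, and a two-layer classification
    head) operating on fixed-geometry log-magnitude STFT spectrogram images,
    together with its training protocol (Adam, stepped learning rate,
    repeated stratified ten-fold cross-validation with seven metrics and 95
    percent confidence intervals), Grad-CAM interpretation with frequency-band
    localization statistics, a classical acoustic feature bank (short-term
    energy, pitch, fluency/pause statistics, long-term average spectrum,
    pooled spectrograms, MFCC, gammatone cepstra, and the linear-prediction
    family LP/WLP/SWLP/XLP at order 38) benchmarked with four classifiers,
    and a source-filter synthesizer that generates labelled two-class speech
    with ground-truth annotations for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    MASS,
    Rcpp,
    class,
    e1071,
    png,
    randomForest,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
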