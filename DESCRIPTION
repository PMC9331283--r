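Package: readtaskdx
Title: Multimodal Reading-Task Features for Schizophrenia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and evaluation for multimodal (speech plus
    video) reading-task screening of schizophrenia. Implements the phonatory
    intensity variation diversity (PIVD) and auditory frequency variation
    coefficient (AFVC) acoustic features of speech emotional flatness,
    landmark-trajectory head-movement features (repeated-reading head-rotation
    ratio RHR, unconscious head-movement degree UHD) with a motion-energy
    baseline, mouth-aspect-ratio fluency image representations (time-domain
    map and short-time Fourier 3-D spectrogram), a frozen-backbone transfer
    feature extractor (RRF), baseline pitch and intensity statistics, a
    repeated stratified cross-validation harness for SVM and random-forest
    classifiers, and a seeded two-group synthetic cohort generator for testing
    the full pipeline without clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
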