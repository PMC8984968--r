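Package: stlstm
Title: Spectral-Temporal Recurrent Decoding of EEG into 2D Cursor Velocities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decodes noninvasive motor-imagery EEG into decoupled horizontal
    and vertical cursor velocities with a spectral-temporal long short-term
    memory (stLSTM) regressor. Spectral features are sliding-window Burg
    autoregressive mu-band (8-13 Hz) power; temporal features are
    error-potential-sensitive first-derivative-of-Gaussian wavelet responses.
    The two streams are right-aligned, concatenated and segmented into fixed
    length sequences, and a two-branch recurrent network is trained under a
    velocity-constrained loss that fits the velocity along the imagined axis
    while suppressing the orthogonal (non-imaginary) component. Includes a
    synthetic EEG generator with lateralized mu-band event-related
    desynchronization and error-locked P300-like deflections, EDF and
    delimited-text trial IO with standard preprocessing, and a trajectory
    level evaluation suite (per-axis RMSE, signed direction accuracy, MAR,
    midline gate success).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    jsonlite,
    yaml,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
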