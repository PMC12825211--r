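Package: stimselect
Title: Movement Selectivity Analysis for Multi-Electrode Peripheral Nerve Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how selectively different peripheral-nerve stimulation
    paradigms (temporal interference versus conventional biphasic pulses) drive
    limb movement, starting from pose-estimation keypoint trajectories.
    Provides a synthetic trial generator with known configuration-to-motif
    ground truth, likelihood-based keypoint filtering and median imputation,
    Euclidean flattening into a standardized position matrix, velocity-based
    movement gating, kNN-graph spectral embedding with density-based and
    k-means clustering, adjusted mutual information with shuffle and
    Gaussian-noise null controls, sticky autoregressive hidden Markov model
    segmentation of movement into behavioral syllables, cosine-metric syllable
    dendrograms, an entropy-based per-configuration selectivity score, and the
    group statistics used to compare paradigms (bootstrap resampling, beta
    regression with a logit link, Mann-Whitney U, Cohen's d, Cliff's delta).
    Also models the 64-channel nerve-cuff configuration space and stimulation
    waveforms (interference envelopes, charge-balanced biphasic trains, charge
    and charge-density metrics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    glmmTMB,
    cluster,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    ggplot2
Config/testthat/edition: 3
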