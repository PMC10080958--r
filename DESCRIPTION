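Package: retstim
Title: Retinal Visual Stimulation Statistics from Head-Mounted Eye-Tracking Sessions
Version: 0.1.0
Authors@R:
    person("retstim", "developers", email = "retstim@example.org", role = c("aut", "cre"))
Description: Quantifies the visual input reaching the retina during natural
    tasks recorded with head-mounted eye trackers (scene camera, eye cameras,
    gaze and inertial streams). Implements gaze-contingent sampling of foveal
    and peripheral retinal regions, spatial and temporal RMS contrast and
    luminance-skewness statistics that proxy ON/OFF pathway stimulation,
    piecewise-linear eye-movement classification (fixation, saccade, smooth
    pursuit, postsaccadic oscillation), a small convolutional eyes-open/closed
    blink classifier, head-velocity-triggered eye-movement averages,
    polynomial-expansion dense optical flow with turn-induced optokinetic
    nystagmus metrics, retinal illuminance in trolands, Gaussian and Alpha
    distribution fits, and deterministic synthetic reading and walking session
    generators with exported ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
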