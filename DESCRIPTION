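Package: kinedecode
Title: Univariate and Multivariate Analysis of Passive-Movement Kinematics in Simulated Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-subject event-related BOLD fMRI experiments with
    factorial passive-finger-movement designs (amplitude x velocity x
    direction), where trial duration is mechanically coupled to the kinematic
    condition, and analyses them end to end: duration-modulated first-level
    general linear models with discrete-cosine high-pass filtering and AR(1)
    prewhitening; searchlight and region-of-interest multivariate pattern
    analysis with leave-one-run-out linear support-vector-machine
    cross-validation; group inference by one-sample t-tests and Welch ANOVA
    with max-statistic permutation family-wise-error control; bootstrap
    confusion-matrix inference, Sidak-corrected pairwise contrasts, and
    leave-one-subject-out stability; and comparison of suprathreshold voxel
    counts across kinematic features with zero-inflated Poisson mixed models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    glmmTMB,
    emmeans,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
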