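Package: idobs
Title: Stochastic Index of Difficulty for Repetitive 3D Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the motor difficulty experienced by an agent performing a
    repetitive three-dimensional end-effector movement. From n repeated trial
    trajectories it computes the average path, the stochastic width profile
    W_obs(s, phi) -- twice the mean radius of the confidence ellipse of trial
    crossings in the plane orthogonal to the mean path at arc length s, scaled by a
    Hotelling T-squared or chi-squared quantile -- and the cumulative stochastic
    Index of Difficulty ID_obs(s*, phi), the integral of 1/W_obs along the path.
    Includes the classical Fitts and MacKenzie indices for comparison, speed-profile
    kinematics, a synthetic reach-transport-return trial generator, and
    repeated-measures comparison of conditions with Bonferroni-corrected post hocs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
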