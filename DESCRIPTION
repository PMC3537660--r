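Package: gobykin
Title: Landmark-Based Cranial Kinematics of Feeding and Climbing in Stream Gobies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based analysis of cyclic cranial kinematics in
    waterfall-climbing gobiid fishes. Reads and validates digitized 2-D landmark
    trajectories from synchronized ventral and lateral high-speed video views,
    registers frames to a stationary pectoral-fin reference, and computes eight
    kinematic variables including a geometric model of oral-sucker area. Each
    variable trace is smoothed with a quintic smoothing spline (generalized
    cross-validation), resampled to 101 percent-cycle increments, and aggregated
    into mean kinematic profiles with standard errors. Groups (species or
    behaviors) are compared with nonparametric rank tests on per-cycle peak
    values and with divergence angles between 101-dimensional mean-profile
    vectors. A deterministic synthetic-motion generator produces parameterized
    feeding and climbing cycles with known ground truth for validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
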