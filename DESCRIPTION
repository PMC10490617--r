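Package: wheelfv
Title: Sprint Force-Velocity Profiling for Wheelchair Athletes from
    Wheel-Mounted IMU Gyroscope Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive horizontal force-velocity (FV) profiles of
    wheelchair athletes from a single wheel-mounted inertial measurement
    unit. A gyroscope angular-rate trace is converted to translational
    velocity, low-pass filtered, cropped to peak speed and fitted with a
    mono-exponential sprint model. Net propulsive force is then estimated
    under two resistive-force models: a generic air-friction model and a
    wheelchair-specific dynamic rolling-friction model with
    velocity-dependent drag and lift constants. Per-sprint outcomes (F0,
    V0, Pmax, decrease ratio of force, FV slope), cohort summaries,
    paired model comparisons and a synthetic-sprint generator with known
    ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    dplyr,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
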