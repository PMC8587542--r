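Package: wbid
Title: Whole-Body Inverse Dynamics from Inertial Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates total and per-foot ground reaction forces and moments,
    and net forces and moments at 14 major joints, from inertial motion
    capture kinematics alone (no force plates). Implements a 15-segment
    scaled rigid-body model with regression-based inertial parameters, a
    recursive Newton-Euler solver run top-down for the upper body and
    bottom-up for the lower body, a velocity-threshold foot contact
    detector, and a convex quadratic program that distributes the total
    ground reaction between the feet during double stance by minimising
    squared net lower-limb joint moments. Includes dynamic and static
    (acceleration-free) model flavours, agreement metrics (RMSE, relative
    RMSE, intraclass correlation), and a synthetic-trial generator with
    exact ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
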