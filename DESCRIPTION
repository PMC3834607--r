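Package: oagait
Title: Lower-Extremity Inverse Dynamics and Knee Muscle Cocontraction in Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A marker-driven gait analysis pipeline for comparing knee muscle
    activity and joint contact loading between subject groups, as in studies of
    medial knee osteoarthritis. Builds a subject-scaled six-segment, 18
    degree-of-freedom lower-extremity model with 26 musculotendon units per
    limb, computes net joint loads at the ankle, knee and hip by bottom-up
    Newton-Euler recursion from marker trajectories and force-plate records,
    resolves muscle redundancy at each cycle point by static optimization of
    summed cubed muscle stress, decomposes the knee joint contact force into
    compressive, medial-lateral and anterior-posterior components, and reports
    extensor/flexor activation and torque cocontraction ratios (EFAR, EFTR)
    with two-sample group statistics. Includes a deterministic synthetic gait
    generator (normal and OA-like modes) standing in for motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
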