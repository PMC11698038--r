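Package: springboard
Title: Jump Energetics of Spring-Actuated Jumpers on Compliant Cantilever Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for latch-mediated spring-actuated (LaMSA)
    jumping from compliant substrates. Reads digitized two-point high-speed
    video trajectories, calibrates cantilever platform stiffness from
    load-deflection tables, derives per-jump kinematics and energetics
    (take-off velocity, elevation relative to the deformed platform plane,
    kinetic energy and power densities, effective leg-spring stiffness via
    conservation of energy), normalizes experimental jumps to per-animal
    control means, and fits the stiffness-regime statistical models
    (one-sample tests and random-intercept mixed models). A coupled
    jumper-platform simulator generates synthetic tracked jumps with ground
    truth so every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
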