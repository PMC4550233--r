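Package: spintirf
Title: Simulation and Analysis of Spinning-Spot Shadowless TIRF Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models a through-the-objective total internal reflection
    fluorescence (TIRF) microscope in which a galvanometer-driven laser
    spot is spun around the objective back focal plane so that
    direction-dependent interference fringes and shadows average out
    within a single camera exposure. Provides galvanometer scan-waveform
    synthesis and frame-by-frame interleave scheduling of up to three
    illumination presets; a physical model of the evanescent excitation
    field (critical angle, penetration depth, back-focal-plane radius to
    incidence angle mapping) with stationary-spot, spinning-spot,
    pseudo-widefield and skimming-plane modes; a synthetic specimen and
    EMCCD camera renderer producing interleaved, mode-tagged image
    stacks; a processing pipeline (black-level subtraction,
    de-interleaving, delta-F/F0 normalization, projections, ROI traces,
    field-uniformity metrics); and event-level analysis of calcium puffs
    recorded in alternating TIRF/widefield frames, including TIRF/WF
    amplitude ratios, site classification and model-based depth
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
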