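Package: gaitmark
Title: Gait Event Detection and Method Agreement for Forward and Backward Treadmill Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects initial-contact and terminal-contact gait events during
    forward and backward treadmill walking from optical-motion-capture marker
    kinematics (foot displacement relative to the pelvis) and from foot-mounted
    inertial sensors (heel accelerometer/gyroscope peak rules, and a
    below-threshold run rule for backward-walking toe sensors), and quantifies
    between-method agreement with mean absolute differences, Bland-Altman 95%
    limits of agreement, two-way random-effects intraclass correlation of
    stride times, and Mann-Whitney comparisons. Includes a synthetic treadmill
    gait simulator with ground-truth events for end-to-end validation, plus
    readers/writers for plain columnar marker, sensor and event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
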