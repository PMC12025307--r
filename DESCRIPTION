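Package: spinegait
Title: Segmental Spinal Rotation Analysis over Standardized Gait Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing transverse-plane segmental spinal rotation
    during treadmill gait measured by dynamic surface topography together with
    foot-pressure recordings. Detects initial-contact and initial-swing events
    from ground reaction force, encodes stance and swing phases, synchronizes
    120 Hz force data with 60 Hz spine frames, time-normalizes gait cycles to a
    0-100 percent scale and pools three or more cycles into one standardized
    gait cycle per measurement via smoothing splines, and derives per-segment
    motion descriptors (symmetry line, level shift, amplitude, point of
    intersection, pairwise phase shifts on the antagonism percentage scale,
    maxima timing relative to stance). Includes a synthetic gait generator so
    the whole pipeline is testable without the proprietary measurement device,
    plus oscillograph visualizations of raw and standardized cycles.
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
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
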