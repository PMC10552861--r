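Package: dishmetry
Title: Single-View Metrology for Plate and Bowl Dimensions from a
    Wearable Camera with Ranging and Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the physical dimensions of eating containers
    (plates, bowls, boxes) from a single egocentric image taken by an
    eyeglass-mounted wearable sensor, without fiducial markers. Combines
    a pinhole camera model with radial lens distortion, an
    accelerometer-derived device pitch, and a time-of-flight distance
    reading to invert the perspective projection onto the tabletop plane
    and measure container widths, diameters and heights in metric units.
    Includes a synthetic scene renderer that forward-projects containers
    of known size into pixel annotations and sensor logs, so that every
    stage of the inverse pipeline is verifiable by round-trip parameter
    recovery, plus a test-bench simulator, error reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
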