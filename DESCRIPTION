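Package: aerialtrack
Title: Drone-Based Athlete Tracking: Calibration, Kinematics and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drone-based electronic performance and tracking systems
    (EPTS): frame-by-frame planar homography calibration of a nadir aerial
    camera from surveyed control points, reconstruction of player field
    coordinates from bounding-box detections, derivation of kinematic
    performance metrics (filtered speed, acceleration, cumulative distance,
    speed-zone distances, cross-correlation synchronization across systems),
    and method-agreement statistics (RMSE, Bland-Altman limits of agreement,
    two-way intraclass correlation coefficients, regression and coefficients
    of variation) for validating positional measurement systems against each
    other.  A scene simulator emulates ground-truth player motion, the aerial
    camera with pose jitter and pixel noise, a GPS stream with Doppler speed
    and an LPS stream, so the full pipeline can be exercised without field
    data collection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
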