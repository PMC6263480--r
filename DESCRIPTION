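Package: canopyscan
Title: Wheat Canopy Height Estimation from LiDAR, Ultrasonic Sensors and
    UAS Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plot-level wheat canopy height estimation and sensor comparison
    for high-throughput field phenotyping. Implements percentile-based height
    extraction from ground LiDAR point clouds with least-squares tilt
    correction and ground-baseline removal, ultrasonic voltage-to-height
    conversion, and UAS-style canopy height models (DSM minus a kriged DTM
    interpolated from sampled soil pixels) with per-plot zonal pixel
    percentiles. Includes an evaluation layer (RMSE, bias, R-squared,
    optimal-percentile search by measurement-method category and plot
    position) and a synthetic field/sensor simulator with recorded ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
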