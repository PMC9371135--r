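Package: aerofog
Title: Aeroponic Greenhouse Monitoring, Water-Stress Analytics and Root
    Image Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained software emulation of an IoT monitoring stack
    for an aeroponic greenhouse. A synthetic device layer generates diurnal
    climate telemetry, nutrient-tank dynamics, fault injections and root
    images with ground truth; fog-layer microservices schedule irrigation
    and cameras, poll sensors into an eight-bit health register, detect
    service and sensor failures and raise alerts; a local time-series
    channel store enforces free-tier rate limits and daily message quotas;
    leaf-to-air vapor pressure deficit (Tetens form) and crop-air
    temperature difference classify water stress; and an HSV segmentation
    pipeline with 2x2 morphological filtering enhances root images. A
    ten-bit parity-protected command vector supports remote operation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
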