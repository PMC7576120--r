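Package: siodscan
Title: Posterior-Pole Geometry and Circumpapillary RNFL Analysis for Situs
    Inversus of the Optic Disc
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates posterior-pole retinal anatomy and analyses
    circumpapillary retinal nerve fiber layer (RNFL) thickness profiles in
    situs inversus of the optic disc (SIOD). Provides a synthetic scene
    generator with an axon-conserving double-hump RNFL thickness field,
    per-eye posterior-pole measurements (foveo-BMO distances, axis angle,
    BMO area, inter-arcade distance), circle-scan profile extraction with
    scan-circle repositioning along the foveo-BMO axis, clock-hour sector
    summaries, age/axial-length case-control matching, and cluster-robust
    (GEE-style) paired-eye group comparisons, orchestrated by a reproducible
    in-silico experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
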