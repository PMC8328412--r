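Package: pikarem
Title: Digital-Twin Simulation of Plateau Pika Activity and Camera-Trap
    Density Estimation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of plateau pika (Ochotona curzoniae)
    ground activity on a Voronoi-tessellated landscape of burrow-system
    territories, with virtual infrared camera traps whose detection zones
    are equal-area isosceles triangles. Implements the random encounter
    model (REM) density estimator, the activity-intensity-per-density
    index lambda = P/D with its closed form v*r*(2+theta)/pi, and Monte
    Carlo parameter sweeps relating true population density to camera
    capture frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
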