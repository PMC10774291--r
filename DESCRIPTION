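Package: kelpDSWT
Title: Cross-Shelf Export of Sinking Kelp Detritus by Dense Shelf Water Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how dense shelf water transport (DSWT) exports
    negatively buoyant kelp detritus past the continental shelf edge. The
    package generates idealized mid-latitude shelf scenarios (bathymetry,
    seasonal density gradients, episodic offshore bottom flow, wind, and a
    kelp-occurrence probability map), classifies per-timestep suitability for
    DSWT from a three-condition criterion (negative cross-shore density
    gradient, potential energy anomaly above a threshold, and gravitational
    stratification outcompeting wind mixing unless winds are onshore), tracks
    bottom-drifting particles with fourth-order Runge-Kutta advection and
    Brownian diffusion, and converts decay-weighted shelf-edge crossings into
    monthly export statistics, per-reef attributions, and an areal carbon flux
    estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
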