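Package: dtlforce
Title: Contractile Force and Force-Length Analysis for Magnetically
    Preloaded Muscular Thin-Film Cantilevers
Version: 0.1.0
Authors@R:
    person("DTL", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers cell-generated contractile force from side-view
    recordings of a deflecting hydrogel cantilever that carries a
    cardiac cell layer, using a quasi-static energy-balance beam model
    (constant-curvature Euler-Bernoulli bending, viscous drag, magnetic
    body load). Includes a semi-analytic model of stacked block-magnet
    actuation with calibration from cell-free deflections, a synthetic
    experiment generator (preload/stimulation schedules, preload
    dependent twitches, rendered silhouette videos), video tracking by
    binarization, midline extraction and per-frame quadratic fits, and
    contractility readouts: normalized stress-strain loops, quasi-static
    force-length relations and a slope-based contractility index with
    bootstrap condition comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
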