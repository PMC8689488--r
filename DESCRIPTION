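Package: rosquant
Title: Whole-Organism ROS Quantification from Multi-Channel Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("rosquant", "developers", email = "rosquant@example.org",
           role = c("aut", "cre"))
Description: Quantifies oxidative stress in translucent juvenile bivalves from
    three-channel confocal z-stacks. Computes per-channel maximum-intensity
    projections, removes non-specific shell autofluorescence from the ROS
    channel by gain-balanced channel subtraction, segments the projected shell
    footprint and the ROS-positive area inside it, and reports the ROS-positive
    area as a percentage of projected shell area per individual. Includes the
    downstream statistical chain (arcsine square-root transform, nested
    one-way ANOVA with replicate container as a random factor nested in
    treatment, Tukey post hoc), a synthetic phantom generator with known
    ground-truth masks for end-to-end validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
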