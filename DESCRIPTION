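Package: slipgait
Title: Neuromechanical Simulation of Slip- and Trip-Induced Falls in Bipedal Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Planar neuromusculoskeletal simulation of human walking and
    friction-dependent falls. An eight-segment rigid-body walker is driven by
    a network of fourteen Matsuoka-type oscillator neurons (a central pattern
    generator) and interacts with the ground through spring-damper contact
    elements whose horizontal force is capped by a static coefficient of
    friction. The package registers three gait parameterizations (young adult,
    elderly non-faller, elderly faller), runs seeded friction-sweep
    experiments with automated classification of slip- and trip-induced
    falls, and computes gait and stability metrics: stride length, walking
    speed, cadence, foot clearances and their coefficients of variation,
    traction (required friction) maxima, and the margin of stability based on
    the extrapolated center of mass. Kinematic fixture generators with known
    ground truth support testing of the analysis stages independently of the
    dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
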