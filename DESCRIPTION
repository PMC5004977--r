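Package: glidebuoy
Title: Body Density and Diving Gas Volume of Breath-Hold Divers from Glide
    Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tissue body density, diving gas volume, a combined
    drag term and tissue compressibility of deep-diving marine mammals from
    biologging tag records. Detects stroke-and-glide locomotion on the
    dorso-ventral accelerometer axis, extracts filtered 5-second glide
    segments, evaluates a hydrodynamic forward model of drag, compressible
    tissue buoyancy and Boyle's-law gas buoyancy, and fits it with
    hierarchical Bayesian MCMC (JAGS) with deviance-information-criterion
    model comparison. Includes a seawater equation of state for ambient
    density profiles from CTD casts and a synthetic tag-data generator with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    signal,
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
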