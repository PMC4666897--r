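Package: forestdist
Title: Estimating Forest Disturbance Intensity from Successive Biomass Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for describing and estimating the intensity of forest
    disturbance from two successive remotely sensed biomass maps. A
    disturbance regime is summarised by the annual per-pixel probability of
    disturbance (E_P) and the fraction of biomass lost per disturbance
    event (E_I); their product approximates the ensemble mean fractional
    biomass loss per year (E_M). The package provides a stochastic
    pixel-ensemble simulator of biomass change (annual growth, Bernoulli
    fractional-loss disturbance, and additive or dB-domain observation
    noise), a simulation-based maximum-likelihood estimator of (E_P, E_I)
    with 95 percent cumulative-likelihood credible regions, and
    reproducible observing-system simulation experiments (OSSEs) that
    score the estimator against known synthetic truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
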