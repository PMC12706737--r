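Package: pcbair
Title: Air-Water Exchange, Passive Sampling, and Dispersion of Airborne PCBs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for source attribution of airborne polychlorinated
    biphenyls (PCBs) around contaminated harbors. Computes congener-specific
    air-water volatilization fluxes from dissolved water concentrations with
    a Whitman two-film mass-transfer model, converts fluxes over a water
    surface to area-source emissions, predicts downwind airborne
    concentrations with a steady-state Gaussian plume area-source model,
    inverts polyurethane-foam passive air sampler (PUF-PAS) masses to
    airborne concentrations via effective volumes and depuration-compound
    sampling rates, and compares predicted and measured air with congener
    profile cosine similarity, distance-decay regression, Moran's I,
    ordinary kriging, and rank-sum tests. Includes a synthetic-data
    generator that emulates the statistical structure of harbor water
    monitoring, summer meteorology, and PUF-PAS field campaigns, plus
    Monte Carlo uncertainty propagation for fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
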