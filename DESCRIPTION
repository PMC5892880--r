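Package: serialRIP
Title: Serial-Crystallography Radiation-Damage-Induced Phasing Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates serial synchrotron crystallography dose-series
    experiments on toy macromolecular crystals and implements the full
    radiation-damage-induced phasing (RIP) inference chain on the simulated
    pools: genetic-algorithm selection of sub-datasets for merging, merging
    statistics (R-merge, R-meas, CC1/2, I/sigma, completeness, multiplicity),
    K-scanned isomorphous difference amplitudes with propagated errors,
    dual-space substructure determination of damage sites, SIR-style phasing
    with solvent-flattening density modification and signed-site
    bootstrapping, and an evaluation battery (model-phased difference-map
    peak heights, substructure correctness under allowed origin shifts and
    hand inversion, weighted mean phase error) as functions of dose, scale
    factor K and multiplicity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml,
    optparse,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
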