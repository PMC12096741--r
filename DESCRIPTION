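Package: airpah
Title: Source Apportionment and Health Risk Assessment of PM2.5-Bound PAHs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for particle-bound polycyclic
    aromatic hydrocarbons (PAHs) measured in daily PM2.5 samples: summary
    and limit-exceedance statistics, molecular diagnostic ratios, a
    from-scratch positive matrix factorization (PMF) receptor model,
    potential source contribution function (PSCF) gridding of back
    trajectories, and Monte Carlo incremental lifetime cancer risk (ILCR)
    with sensitivity analysis.  A synthetic-data generator with known
    latent source structure makes every stage testable without access to
    monitoring data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
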