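Package: trajcompare
Title: Statistical Similarity of Molecular Dynamics Trajectories at
    Residue Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies statistical similarity between pairs of molecular
    dynamics trajectories from local Calpha fluctuation variables.
    Distributions of on-residue displacement magnitudes and residue-pair
    distances are estimated with a nonparametric maximum-entropy method
    scored against sampled uniform random data through order statistics.
    Eight similarity measures (RMSF difference, Jensen-Shannon divergence,
    L1 distance, three Kullback-Leibler-type bands, one-sample and
    zero-sample Kolmogorov-Smirnov statistics) are computed per residue or
    residue pair, collapsed onto the backbone by nearest-neighbour
    averaging, averaged over half-trajectory block pairings, and converted
    to per-residue log10 p-value significance profiles. A synthetic-data
    module generates Gaussian mock trajectories, autocorrelated dynamics
    and frame-shuffling controls for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    data.table,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
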