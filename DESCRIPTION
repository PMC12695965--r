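Package: entolidar
Title: Insect Diversity Estimation from Entomological Lidar Backscatter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for entomological lidar recordings: extraction
    of individual insect transits from raw time-range backscatter blocks,
    Welch modulation power spectra of wingbeat oscillations on a fixed
    frequency axis, memory-efficient Ward hierarchical clustering with a
    parameter-free, noise-referenced cluster-count criterion, rank-abundance
    and detection-range model fits, and counting of unique spatial and diel
    activity patterns. Includes a ground-truthed synthetic scene generator
    (multi-species wingbeat ensembles, Gaussian transit envelopes, rank-
    abundance compositions, range-occupancy profiles, diel niches and
    instrument noise) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
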