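Package: permeon
Title: In-Silico Electrophysiology of Ion Channel Permeation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ion permeation through membrane channel
    pores, built around tabular per-ion trajectories. Detects complete
    permeation events, estimates single-channel conductance from event counts
    under a transmembrane voltage (with windowed standard errors) and
    selectivity ratios from event totals, computes axial ion densities and
    negative-log-density energy profiles with binding-site detection,
    first-solvation-shell water counts, inter-site permeation cooperativity as
    excess state-specific information (mutual information between occupancy
    transition streams above a shuffle-derived noise threshold), and potentials
    of mean force from umbrella-sampling windows by self-consistent WHAM with
    block-analysis errors. A Brownian-dynamics generator produces synthetic
    pore trajectories, umbrella windows, coupled occupancy series and water
    configurations so the whole pipeline is testable without molecular
    dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
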