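Package: connharmony
Title: Information-Theoretic Assessment of Multi-Site Connectome Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phase-interaction connectomes from multi-site resting-state
    BOLD time series, removes acquisition-site effects with ComBat, CovBat or a
    traveling-subject measurement-bias model, characterizes each subject's
    network with normalized Shannon entropy and Fisher information on the
    Shannon-Fisher plane, and quantifies residual site effects with a
    Kruskal-Wallis criterion. Includes a fully seeded multi-site cohort
    simulator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
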