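Package: latifundia
Title: Coupled Land-Use, Land-Trade and Disease Dynamics of Latifundia Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the concentration of land ownership (latifundia) in a
    population of landowners whose parcels cycle between forest, agriculture
    and post-agricultural recovery, and who trade recovering land under
    pre-capitalist rules: each owner's purchasing power is their share of the
    population's total land utility, and sale pressure is its complement (or a
    mean/median asset rule). A frequency-dependent susceptible-infected-
    susceptible process can discount the utility of infected owners, coupling
    disease transmission to land-tenure inequality. Provides the yearly
    simulator, a two-owner fixed-purchasing-power analysis, Monte-Carlo sweep
    drivers over system size, utility orderings, transition rates and disease
    scenarios, tidy result tables, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
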