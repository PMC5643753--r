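Package: axonhop
Title: Coulomb-Force Channel-Hopping Model of Conduction in Unmyelinated Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models action-potential conduction in unmyelinated axons as a
    sequence of threshold-crossing hops between rings of voltage-gated sodium
    (NaV) channels, driven by the Coulomb force of sodium influx at the
    previously opened channel. Provides the channel-lattice geometry on a
    cylindrical axon with closed-form, Riemann-sum and Monte-Carlo hop-distance
    averages, Goldman-Hodgkin-Katz membrane potentials and per-action-potential
    charge budgets, a per-channel time-budget feasibility report, a
    discrete-event conduction simulator, and sweep engines that recover the
    scaling of conduction velocity with the square root of channel density and
    of axon diameter. Results are tibbles with broom-style tidiers and ggplot2
    autoplot methods; a thin command-line interface covers the common runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
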