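Package: ddaflux
Title: Steady-State Carbon and Nitrogen Flux Model of Diatom-Diazotroph
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained cell flux model of a diatom-diazotroph
    association (DDA) with ammonium uptake. Solves the steady-state
    elemental mass balance of carbon and nitrogen for one association
    (host diatom plus cyanobacterial trichomes of vegetative cells and
    heterocysts), resolving photosynthesis, Monod ammonium uptake, N2
    fixation and its carbon cost, and the signed carbon and nitrogen
    transfers between the partners. Includes allometric volume-to-carbon
    quotas, closed-form no-transfer and zero-fixation ammonium
    thresholds, light-limited photosynthesis, parameter sweeps,
    element-fate percentage budgets, named sensitivity variants, a YAML
    configuration layer and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
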