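Package: stovecba
Title: Probabilistic Cost-Benefit Analysis of Improved Cookstove Adoption
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Household-level Monte Carlo cost-benefit simulator for the
    transition from traditional biomass cookstoves to improved or modern
    alternatives (improved wood, charcoal, kerosene, LPG, electric).
    Implements a deterministic monthly cost-benefit model (annualized
    capital, program, maintenance, net fuel, and learning costs against
    morbidity, mortality, cooking-time, carbon-emission and forest
    benefits), uncertainty propagation over roughly thirty uniformly
    distributed parameters with rank correlations induced by the
    Iman-Conover method, one-way tornado sensitivity analysis, and policy
    scenarios contrasting private and social perspectives, capital
    subsidies, carbon-offset transfers and two carbon-accounting variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
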