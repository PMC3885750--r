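Package: pahpopex
Title: Monte Carlo Population Exposure and Lung Cancer Risk Model for Airborne PAHs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates population inhalation exposure to the 16 USEPA priority
    polycyclic aromatic hydrocarbons (PAHs) with a microenvironment time-activity
    model: seasonal outdoor concentrations are sampled from lognormal
    distributions, indoor concentrations follow a single-zone steady-state mass
    balance with infiltration, penetration, particle deposition, indoor emission
    sources (smoking, cooking fuel) and optional air cleaning, and individual
    exposures are standardized to benzo[a]pyrene equivalents via toxic
    equivalency factors. Lifetime exposure concentrations are converted to lung
    cancer relative risk through a unit-relative-risk model, and scenarios are
    compared by population attributable fraction (PAF) and potential impact
    fraction (PIF). Ships the 15 baseline and intervention scenarios of the
    Beijing 2006 application (smoking bans, clean cooking fuel, atmospheric
    cleaning, cooking exhaust, indoor particle cleaners), an exposure-pattern
    decomposition (IN-in, OUT-in, OUT-out), and one-at-a-time sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
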