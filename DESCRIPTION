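Package: cwrmigrate
Title: Individual-Based Simulation of Salmonid Migration Through
    Cold-Water Refuges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates upstream migration of adult summer steelhead and fall
    Chinook Salmon through a dammed river corridor whose thermal landscape
    ("thermalscape") includes tributary cold-water refuges.  An hourly
    individual-based engine couples probabilistic behavioural
    thermoregulation, dam tailrace and fishway passage, and a
    respiration-only Wisconsin-style bioenergetics sub-model.  Synthetic
    temperature fields, cohorts, and a nine-refuge river map allow the full
    four-thermalscape experiment (current/future x refuges
    available/unavailable) to run with no external data.  Outcome analytics
    include degree-day exposure above 20-22 degree C thresholds, percent
    energy used, acute and energetic mortality, arrival timing, and
    highest-density-region coverage of energy-conserving phenotypic space.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
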