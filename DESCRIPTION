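Package: gliaflux
Title: Constraint-Based Modeling of Astrocyte Metabolism Under
    Inflammation and Steroid Treatment
Version: 0.1.0
Authors@R:
    person("gliaflux", "maintainers", email = "gliaflux@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis (FBA) toolkit for simulating astrocyte
    metabolism under three scenarios: healthy, palmitate-induced
    inflammation, and tibolone treatment under inflammation. Provides
    domain types for compartmentalized metabolic networks, a
    deterministic bounded-variable simplex solver, parsimonious and
    lexicographic FBA, flux variability and blocked-reaction detection,
    expression-proportional bound constraining with gene-protein-reaction
    (GPR) rules, additionCost gap filling, medium application,
    robustness-based IC50 estimation, fold-change comparison between
    scenarios, knockout-based classification of pro-/anti-inflammatory
    and treatment-essential reactions, and a synthetic astrocyte-like toy
    network with engineered ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
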