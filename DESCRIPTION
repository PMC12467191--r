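Package: fibroburden
Title: Global Fibrosis-Related Disease Burden Trends, Inequality Metrics, and Frontier Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the global burden of fibrosis-related diseases
    from GBD-style country-year-cause estimate tables. Computes cause-share
    proportions of total burden and percent changes in age-standardized rates,
    the slope index of inequality (SII) from population-weighted midpoint
    socio-demographic index (SDI) ranks, the concentration index of inequality
    (CII) by trapezoid integration of the Lorenz-type concentration curve, and
    a non-parametric frontier (minimum achievable burden) analysis with
    per-country efficiency gaps. Includes a seeded synthetic panel generator
    emulating the statistical structure of GBD exports so every stage is
    testable without downloads, and a pipeline orchestrator with
    machine-readable manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
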