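Package: seghealth
Title: Residential Segregation and Racial Inequities in Self-Rated Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether city-level residential segregation
    modifies racial inequities in fair/poor self-rated health. Computes
    income- and race-based dissimilarity indices from census-tract counts,
    builds a city social-environment composite from infrastructure and
    education indicators, fits random-intercept (city) logistic regression
    models with city-level cluster-robust variance, and converts fitted
    models into marginally standardized prevalences, prevalence ratios and
    prevalence differences, overall and stratified by segregation tertile.
    A synthetic-data module generates tract tables, city indicators and
    individual survey records with known ground truth so the full analysis
    chain can be exercised and validated without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    yaml
Config/testthat/edition: 3
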