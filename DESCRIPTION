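Package: resilmcda
Title: Weighted Survey Aggregation and SMART Multi-Criteria Decision
    Analysis for Health-System Resilience Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage decision pipeline for pandemic-preparedness planning
    from healthcare-professional surveys. Stage one aggregates Likert-scale
    questionnaire responses under differentiated respondent weight
    coefficients (education, experience, pandemic role) into per-item
    weighted indices, preferred responses and dispersion summaries, and maps
    them onto risk/opportunity criteria. Stage two evaluates candidate
    resilience strategies with the Simple Multi-Attribute Rating Technique
    (SMART): criterion scores normalized into weights, a rank-based
    performance matrix, a linear additive utility U_j = sum_k w_k * u_jk,
    optimal-alternative selection, and one-at-a-time weight-sensitivity
    analysis. Includes Cochran sample-size arithmetic and a synthetic-survey
    generator with stratified demographics and planted modal responses so
    the full pipeline is testable without access to raw questionnaire data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
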