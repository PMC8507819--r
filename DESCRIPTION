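Package: rulatime
Title: Automated RULA Scoring and Time-Weighted Ergonomic Risk Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-wise Rapid Upper Limb Assessment (RULA) scoring of
    joint-angle time series from seated (dental) work, time-in-score exposure
    statistics (relative average risk score over time and ergonomic risk
    potential), and the nonparametric comparison design used to contrast
    workplace concepts and occupations (Friedman test with Conover-Iman
    post-hoc and Bonferroni-Holm correction, Mann-Whitney U tests). Includes
    a seeded semi-Markov posture simulator that generates paired
    dentist/assistant cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
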