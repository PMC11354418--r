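Package: cohortDD
Title: Cohort Life Tables and Degree-Day Demography for Insect Mass Rearing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic analysis of insect mass-rearing cohorts on a
    degree-day clock. Reads individual-level rearing logs and daily
    temperature series, accumulates degree-days above a base temperature
    from an egg biofix, builds stage-structured cohort life tables with
    degree-day life expectancy, estimates per-diet population trends, and
    runs the comparison battery used in rearing trials (sex-ratio
    chi-square with residual post hoc, exact mortality tests, Welch ANOVA
    with Games-Howell, per-instar Kruskal-Wallis, and two-way fecundity
    ANOVA). Includes a seeded stochastic cohort generator calibrated to
    published rearing trials of the assassin bug Zelus renardii, so the
    whole pipeline is testable without access to raw laboratory logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
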