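Package: nuptiality
Title: Net Nuptiality Tables and Determinants of First-Marriage Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds province/sex/residence-specific net (multi-decrement)
    nuptiality tables from age-specific first-marriage and mortality rates,
    derives expected years in the never-married state and the expected
    duration of singlehood since birth, and estimates determinants of
    first-marriage age with two-way fixed-effects panel regressions and
    province-clustered standard errors.  Includes a parametric mortality
    model calibrated to a target life expectancy, synthetic census-like
    data generators with known ground truth, a discrete-time cohort
    microsimulation oracle, profile clustering, gap tables and global
    Moran's I for cross-province summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
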