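Package: chronoveg
Title: Chronosequence Analysis of Woody Vegetation Structure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of woody-plant community structure along a
    land-abandonment chronosequence: stem-level inventory handling with a
    basal-diameter census rule, species richness, Shannon diversity and the
    effective number of species, Pretzsch's species height profile index
    (A-index), importance value index tables and stand volume, Bray-Curtis
    similarity with UPGMA clustering, cophenetic correlation and bootstrap
    branch support, and assumption-gated group comparisons (classic or Welch
    ANOVA with Tukey HSD or Games-Howell post hoc). Includes a seeded
    synthetic inventory generator emulating a four-stage Tamaulipan
    thornscrub chronosequence and a reference site-level density table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
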