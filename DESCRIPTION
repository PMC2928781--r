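Package: tetramap
Title: Tetrad Analysis of Meiotic Crossing Over, Interference, and Spore
    Viability in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic analysis of Saccharomyces cerevisiae
    tetrad dissection data: per-marker segregation classification (2:2
    versus gene-conversion classes), parental ditype / tetratype /
    nonparental ditype interval classification, Perkins map-distance
    estimation with delta-method standard errors, single-spore
    recombination frequencies with Wilson score confidence intervals,
    crossover-interference statistics (coefficient of coincidence with a
    continuity-corrected binomial test, and the NPD-ratio test with both
    Papazian and maximum-likelihood expected nonparental-ditype counts),
    spore-viability profiles and chromosome-III nondisjunction
    signatures, Fisher exact strain comparisons, and a counting-model
    meiosis simulator with controllable crossover interference, gene
    conversion, and obligate-crossover-failure nondisjunction that emits
    dissection tables in the same format the analysis functions consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
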