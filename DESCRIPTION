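Package: meiocross
Title: Crossover Scoring, Tetrad Inference and Interference Analysis for
    Multi-Marker Testcrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing meiotic crossing over from multi-marker
    testcross progeny, as used in Drosophila recombination genetics.
    Scores per-interval crossovers from progeny phenotype vectors, builds
    replicate-cross genetic maps with t-test comparisons, profiles
    rate-independent crossover patterning with chi-square heterogeneity
    tests, infers tetrad exchange-class distributions by the classical
    Weinstein algebraic method with dispersion diagnostics, and estimates
    crossover interference via the coefficient of coincidence. A forward
    simulator of female meiosis (explicit exchange distributions, Poisson,
    or a counting-model interference process, with optional crossover
    assurance and a non-interfering class II pathway) generates synthetic
    progeny tables with ground truth for validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
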