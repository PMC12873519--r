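Package: leafxylem
Title: Leaf Length and Twig Xylem Vessel Diameter Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how leaf length relates to xylem vessel
    diameter in angiosperm twigs. Implements a Poiseuille stacked-conduit
    resistance model with power-law tip-to-base widening and a
    resistance-balancing terminal-diameter model; log10-log10 allometric
    scaling regressions with a Welch test for slope differences and
    leaf-type/site interaction models; phylogenetic signal statistics
    (Pagel's lambda, Blomberg's K) and generalized least squares under
    white-noise, Brownian-motion and Ornstein-Uhlenbeck correlation
    structures with AICc model selection; and a seeded synthetic generator
    of species trait tables and pure-birth ultrametric phylogenies that
    emulates the statistical structure of real cross-species samples.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
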