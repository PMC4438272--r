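Package: apsite
Title: Energetics of the Alkaline Phosphatase Active-Site Residue Network
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of the combinatorial (2^5) mutant
    landscape of five Escherichia coli alkaline phosphatase active-site
    residues (D101, R166, D153, E322/Mg2+, K328). Provides fold-effect and
    transition-state free-energy (ddG) arithmetic, additivity predictions
    and double-mutant-cycle couplings, a ten-parameter multiplicative
    functional-unit model of catalytic efficiency (kcat/KM) fit by least
    squares or Chebyshev (minimax) criteria, enumeration and
    dynamic-programming counts of selectively accessible mutational
    pathways on the residue hypercube, and birth-death Markov mean
    first-passage waiting times comparing cooperative and stepwise modes
    of active-site evolution. Includes a synthetic-landscape generator
    with log-normal measurement noise for end-to-end validation and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
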