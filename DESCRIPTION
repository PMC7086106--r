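Package: matesys
Title: Mating-System Analysis from Microsatellite Parentage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse polygynous mating systems from codominant
    marker data: locus quality control (heterozygosities, polymorphic
    information content, exact Hardy-Weinberg tests, replicate-based
    genotyping-error rates), likelihood-based paternity assignment under
    an allelic-dropout/misprint error model with posterior confidence and
    temporal feasibility filters, maximum-likelihood and moment estimators
    of pairwise relatedness, reproductive-skew statistics (Nonacs' binomial
    index B with a residence-weighted Monte-Carlo null), Bateman gradients,
    and a rank-correlation screen of fitness correlates. A pedigree
    simulator with allelic dropout generates calibrated synthetic data
    sets, including the three power-analysis scenarios used to validate
    the paternity-assignment design, so the whole pipeline can be
    exercised without external data.
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
    optparse
Config/testthat/edition: 3
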