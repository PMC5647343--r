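Package: driftscape
Title: Drift Robustness on Two-Peak Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying drift robustness: the evolution of small
    populations toward fitness peaks whose mutational neighbourhoods are
    depleted of small-effect deleterious mutations. Implements the exact
    origin-fixation Markov chain on minimal and extended two-peak genotype
    landscapes with Kimura and Sella-Hirsh fixation kernels and closed-form
    and numeric critical population sizes; a Monte-Carlo sampler of the
    origin-fixation chain; a synthetic genotype-to-fitness landscape
    generator with lethal, small-effect, large-effect, neutral and epistatic
    modifier site classes; a forward-time Wright-Fisher simulator with
    genealogy and line-of-descent tracking; and the distribution-of-fitness-
    effects and line-of-descent analysis pipeline (mutation classification,
    maintained beneficial mutations, equal-fitness cohorts, epistatic
    signatures, treatment comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    seqinr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
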