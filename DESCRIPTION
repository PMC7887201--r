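Package: lmcbreed
Title: Look-Ahead Monte Carlo Parental Selection for Trait Introgression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of marker-assisted backcross breeding
    programs for introgressing donor trait alleles into an elite recurrent
    parent. Provides a diploid meiosis model (first-order Markov
    recombination chain, no interference), exact gamete-probability
    computation, three parental-selection metrics - background genomic
    estimated breeding value, predicted cross value, and a look-ahead
    Monte Carlo score that simulates descendant backcross paths to the
    selfed terminal generation - plus a replicated pipeline runner,
    synthetic inbred parent-pair generators at a target Nei similarity,
    TSV/YAML input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
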