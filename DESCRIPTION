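Package: gcsweep
Title: Gene-Culture Coevolution: Cultural Hitchhiking, Selective
    Interference and Sweep Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of gene-culture coevolution for a haploid genetic locus
    and a vertically transmitted binary cultural trait. Implements the exact
    one-generation transmission engine for affinity-biased and cultural
    trait-biased vertical transmission, closed-form deterministic recursions
    for cultural hitchhiking at a neutral locus, finite-population
    Wright-Fisher simulations of gene-culture selective interference, an
    agent-based multilocus simulator of secondary hitchhiking around a
    gc-pseudolinked locus, haplotype homozygosity statistics (H1, H2, H2/H1)
    for distinguishing hard, soft and cultural sweeps, and a numerical solver
    for the fixation probability of a beneficial mutation arising during a
    cultural sweep.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
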