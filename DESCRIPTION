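Package: morphoclock
Title: Bayesian Morphological-Clock Tip-Dating with Fossilized Birth-Death Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Bayesian tip-dating of morphological character matrices
    under the Mkv model with ascertainment correction, uncorrelated (IGR) and
    autocorrelated (TK02) relaxed morphological clocks, and fossilized
    birth-death (FBD) tree priors including skyline variants and four
    taxon-sampling strategies (fossiltip, random, diversity, and diversity
    without sampled ancestors). Includes a Metropolis-Hastings MCMC engine with
    sampled-ancestor reversible-jump moves and convergence diagnostics (ASDSF,
    PSRF, ESS), stepping-stone marginal-likelihood estimation and Bayes
    factors, majority-rule consensus and maximum-compatibility tree summaries
    with highest-posterior-density node ages and relative branch rates,
    partition-rate regression reports for tests of evolutionary integration,
    validation-grade Fitch parsimony with implied weighting, and a forward
    simulator of fossilized birth-death time trees and clocked morphological
    matrices for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    coda,
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
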