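Package: deimmunize
Title: Population-Specific Protein De-Immunization by Exact Bi-Objective Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs mutants of a therapeutic protein that trade off HLA
    class II epitope immunogenicity, weighted by the allele frequencies of a
    target population, against evolutionary sequence fitness from a pairwise
    maximum-entropy (Potts) model of the protein family. Provides alignment
    filtering and reweighting, pseudo-likelihood inference of fields and
    couplings, evolutionary-coupling scores with average product correction,
    position-specific scoring matrix epitope scanning with hinge-loss
    immunogenicity, the mixed-integer encoding of the design problem, and an
    exact parallel two-phase rectangle-splitting solver that returns the full
    Pareto front of designs with proven optimality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
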