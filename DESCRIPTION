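Package: sweepabc
Title: Two-Population ABC Inference of Selective Sweeps at a Focal Variant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximate Bayesian computation (ABC) inference of the selection
    regime acting on a focal biallelic variant shared by an African and a
    non-African population: neutrality (NTR), a sweep from a de novo mutation
    (SDN), or a sweep from standing variation (SSV), with configurable dominance.
    Provides a rescaled Wright-Fisher trajectory simulator with selection,
    migration and drift under a two-deme out-of-Africa demography, a
    trajectory-conditioned structured-coalescent haplotype simulator for linked
    neutral variation, the within- and between-population summary statistics
    used for sweep detection (pairwise diversity, Watterson's theta, Tajima's D,
    Fay and Wu's H, Weir-Cockerham and Reynolds F_ST, EHH/iHH, raw iHS and
    XP-EHH, empirical p-values against score distributions), PLS-based summary
    reduction, rejection-ABC model choice with Bayes factors, posterior
    parameter estimation, cross-validation power assessment, and
    dominance-model comparison, together with readers and writers for phased
    VCF subsets, ms-format haplotype blocks, HapMap-style genetic maps and
    structured run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    mixOmics,
    vcfR,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
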