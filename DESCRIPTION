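Package: siderotrait
Title: Siderophore Trait Distributions Under Copper Stress
Version: 0.1.0
Authors@R:
    person("Compost", "Microbiome Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how copper stress reshapes siderophore production in
    a compost bacterial community and a focal Pseudomonas fluorescens strain.
    Converts chrome azurol S (CAS) plate reads into standardized siderophore
    scores, computes Malthusian growth rates and relative-fitness statistics
    from mono- and co-culture assays, screens genus-level copper effect sizes
    (Cohen's d against baseline production, Spearman rank correlation), and
    fits a hierarchical Bayesian heteroscedastic linear model with
    replicate-level random means, group-specific residual standard
    deviations, MAP point estimates, highest-posterior-density intervals,
    derived posterior contrasts, and Pareto-smoothed importance-sampling
    leave-one-out (PSIS-LOO) selection among residual-variance structures.
    Includes a seeded synthetic-data generator that emulates the factorial
    microcosm design, so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
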