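Package: randinfer
Title: Randomization-Model Inference for Two-Arm Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for randomization-based (design-based) inference in two-arm
    clinical trials under unit-treatment additivity. Implements sequential
    treatment-assignment rules (complete randomization, permuted blocks,
    Efron-type and threshold biased coins, marginal-balance minimization, urn
    designs, Pocock-Simon minimization, and arm-combining designs for unequal
    allocation), exact computation of assignment-vector moments by dynamic
    programming and full enumeration, Monte Carlo rerandomization, the
    randomization-model treatment-effect estimator with unconditional and
    conditional variance estimation, randomization tests, comparison with
    ordinary linear-model analysis, and diagnostics for designs whose
    unconditional assignment probabilities drift from the planned allocation
    fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
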