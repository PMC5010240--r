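Package: plreduce
Title: Profile-Likelihood Identifiability Analysis and Model Reduction for ODE Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits ordinary-differential-equation reaction-network models to
    time-resolved data by deterministic multi-start maximum likelihood with
    forward sensitivities, computes the profile likelihood of every free
    parameter, classifies parameters as identifiable, practically
    non-identifiable or structurally non-identifiable, analyses parameter
    coupling along profiles, and proposes and applies data-driven structural
    model reductions (state lumping, reaction removal, algebraic substitution,
    parameter fixing) validated by likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
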