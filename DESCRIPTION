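Package: sleepkin
Title: Kin-Selection Models of Sleep in Group-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the social evolution of sleep under kin
    selection. Implements a tribe-splitting island model with sex-biased and
    budding dispersal: exact neutral identity-by-descent recursions yielding
    whole-genome and parent-of-origin relatedness coefficients, a
    direct-fitness kernel with selection gradients and Hamilton's-rule
    decomposition, convergence-stable sleep optima for monomorphic,
    sex-specific, and parent-of-origin gene classes, loudest-voice-prevails
    genomic-imprinting predictions with a perturbation (deletion, epimutation,
    uniparental disomy) phenotype table, and a compiled individual-based
    simulator used as an independent verification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
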