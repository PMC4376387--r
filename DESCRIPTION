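Package: clskinetics
Title: Kinetic Classification of Cofactor Action in Steroid-Regulated Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Repress", "Kinetics Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Equilibrium mass-action modelling of gene induction and
    repression built around the concentration-limited step (CLS).  Provides
    closed-form linear-fractional dose-responses for arbitrary reaction
    chains with accelerators and six classes of decelerator, symbolic
    derivation of the dose-response parameters (Amax, Amin, IC50 and
    Amax*IC50/Amin) as linear-fractional functions of cofactor amount for
    every admissible receptor/cofactor configuration, a rule engine that
    maps qualitative parameter-plot signatures to mechanism and position
    calls, feasibility analysis localising the steroid receptor relative to
    the CLS, and Metropolis-Hastings/BIC comparison of the predicted,
    permuted and unconstrained linear-fractional model structures.  A
    synthetic competition-assay generator with known ground truth makes the
    whole inference pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
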