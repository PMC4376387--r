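# clskinetics

Kinetic classification of transcription-cofactor action in
steroid-regulated gene expression, built around the
**concentration-limited step (CLS)** — the steady-state analogue of a
rate-limiting step.

## The problem

Gene induction and repression by steroid receptors such as the
glucocorticoid receptor (GR) involve long chains of complex-building
reactions whose intermediates are mostly unobservable.  Classifying a
cofactor as "coactivator" or "corepressor" by whether total output rises
or falls is mechanistically uninformative: an enzymatic-inhibitor-like
factor can raise output and an activator-like factor can lower it.
`clskinetics` implements a mass-action equilibrium theory in which each
factor is classified *kinetically* — as an **accelerator** (combines with
the previous product to form the next, affinity `q`) or one of six
**decelerator** types (binds the accelerator with strength `γq′` and/or
the product with strength `αq′`, the bound product retaining partial
productivity `β`; competitive `α = 0`, uncompetitive `γ = 0`,
noncompetitive `α = γ`, each linear `β = 0` or partial `β > 0`) — and
*positionally*, relative to the CLS and to the other titrated factor.

In the CLS regime every dose-response is **linear-fractional**
(first-order Hill),

    A(S) = (Amax + Amin·S/IC50) / (1 + S/IC50),

and the four parameters `Amax`, `Amin`, `IC50` and the combination
`Amax·IC50/Amin` are themselves linear-fractional functions
`y = (a + bx)/(c + dx)` of any cofactor amount `x`.  The qualitative
shape of those four parameter plots (direction by the `ad` vs `bc` rule,
origin behaviour, half-max orderings) identifies the mechanism and
position of the titrated cofactor — and, through a feasibility analysis,
of the receptor itself.

## What the package provides

- **kinetic core** — reaction chains with accelerators, decelerators and
  oligomer pre-steps; exact equilibrium solving (the brute-force oracle)
  and the closed-form linear-fractional reduction `A = V[Y0]/(1+W[Y0])`;
  CLS-regime diagnostics; four-parameter Hill fits; irreversible
  "hit-and-run" scheme equivalents.
- **configuration formulas** — enumeration of the 18 admissible
  (GR, cofactor) configurations; symbolic derivation of
  `A = T(S)/U(S)` with `T`, `U` linear in `S` and in the cofactor
  amount; the four compatibility conditions tying the parameter plots
  together, checked as exact polynomial identities.
- **dose-response fitting** — the two-stage repression fit (vehicle-well
  `Amax`, Michaelis-Menten stage two), grid normalisation to the lowest
  reporter/cofactor cell, Western-blot linearisation, nested-shape
  parameter-plot fits scored by BIC, and qualitative plot signatures.
- **classification** — the 22-entry prediction rule table (shipped as
  JSON data), and the analytic + stochastic feasibility scan that
  localises GR by intersecting evidence across cofactors.
- **Bayesian model comparison** — Metropolis-Hastings sampling (Rcpp) of
  the predicted (8 parameters), permuted (8) and unconstrained (12)
  linear-fractional model structures, `BIC = χ² + k·ln n`, posterior
  half-max ordering probabilities.
- **synthetic data** — a competition-assay generator (4×4 reporter ×
  cofactor grids, four steroid doses, triplicates, log-normal noise)
  with known ground truth for every configuration, driving end-to-end
  recovery studies.
- **pipeline** — `run_pipeline()` / `run_pipeline_cli()`:
  simulate → fit → classify → compare → report, deterministic by seed.

## Worked example

The three-reaction induction chain with the CLS at step 2
(`q = (1, 0.01, 1)`, all accelerator totals 1, activity from the terminal
product):

```r
library(clskinetics)
ch <- reaction_chain(
  list(reaction_step(1, 1), reaction_step(0.01, 1), reaction_step(1, 1)),
  cls_index = 2, inducer_conc = 1, activity_weights = c(0, 1))
cf <- closed_form_dose_response(ch)
attr(cf, "Amax")   # 0.009803922  = 0.01/1.02
attr(cf, "EC50")   # 0.9803922    = 1/1.02
```

A full simulated analysis of a TIF2-like coactivator (accelerator after
the CLS) repressed by GR acting as an accelerator after it:

```r
res <- run_pipeline(list(
  simulate = list(
    configuration = list(factor_mech = "A", factor_pos = "after",
                         gr_mech = "A", gr_pos = "after",
                         order = "GR-after-F"),
    endogenous = 2.7, design = list(n_experiments = 4)),
  mcmc = list(iterations = 20000)), seed = 7)
print(res)
#> signature: Amax inc, Amin dec, IC50 dec, ratio const; Amax>Amin: TRUE
#> rule-table entries fired: 7, 10, 12, 14, 19, 20
#> surviving configurations (1):
#>   factor: accelerator after CLS; GR: accelerator after CLS (GR-after-F)
#> model comparison (BIC): best = predicted
#>          model  k  n   chi2_min        bic acceptance
#>      predicted  8 64   37.97271   71.24377     0.1731
#>  unconstrained 12 64   34.85254   84.75913     0.2123
#>       permuted  8 64 3507.90293 3541.17400     0.1776
```

Reading the output: `Amax` rises while `Amin` and `IC50` fall with added
cofactor and repression is real (`Amax > Amin`); the feasibility scan
finds exactly one of the 18 (mechanism, position) configurations able to
produce that pattern — the generating one.  The predicted model
structure (compatibility conditions built in) beats the permuted and
unconstrained structures on BIC, as it should on data generated by the
theory.

## Command-line pipeline

```sh
Rscript inst/scripts/run_pipeline.R --config cfg.json --seed 1 \
    --outdir out [--mode repression|induction] [--full-scale-mcmc]
```
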