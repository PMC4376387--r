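---
title: "Methods: kinetic classification of cofactor action around the concentration-limited step"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic classification of cofactor action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clskinetics)
```

## The model

Gene expression is modelled as a chain of equilibrium complex-building
reactions `Y[i-1] + X[i] <-> Y[i]` with affinity constants `q[i]` and
total accelerator pools `X[i]^T`, driven by an inducer concentration
`[Y0]`.  At steady state `[Y_i] = q_i [X_i] [Y_{i-1}]`, and each
accelerator obeys a mass-conservation sum over every complex that
contains it.  In general the resulting dose-response is not first-order
Hill.  It becomes exactly **linear-fractional** when the conservation
sums are bilinear, which happens in the **concentration-limited-step
(CLS) regime**: one step's accelerator is limited with respect to its
binding affinity (`q_c·X_c^T << 1`) while every downstream accelerator
remains in excess, making all post-CLS reactions pseudo-first-order.
Measured activity is a weighted sum of the product concentrations at and
after the CLS; the package includes the CLS product itself in that sum
by default (`include_cls_product = TRUE`), matching the worked
three-reaction reduction, and exposes the choice as an option.

Decelerators attach to a step and bind the accelerator (strength
`γq′[D]`), the nascent product (strength `αq′[D]`), or both; the bound
product re-enters the chain with efficiency `β ∈ [0, 1]`.  The six
canonical types are {competitive `α = 0`, uncompetitive `γ = 0`,
noncompetitive `α = γ`} × {linear `β = 0`, partial `β > 0`}.  The free
decelerator concentration is treated as a fixed external parameter (the
decelerator in excess), so no conservation equation is written for it.
One consequence worth knowing: a **partial uncompetitive** decelerator
can *raise* activity — with `γ = 0` the accelerator pool is untouched,
the free product concentration is pinned by equilibrium, and the
β-productive bound complex is additional output.  This is consistent
with the theory's starting observation that enzymatic-inhibitor-like
factors can increase total response; the monotone-decrease property is
asserted (and holds) for the linear types only.

### Two routes to the dose-response

* `solve_equilibrium_numeric()` solves the full nonlinear system — exact
  conservation sums, no CLS approximation — by damped Newton iteration on
  log concentrations with a three-point multistart.  It is the package's
  independent oracle.
* `closed_form_dose_response()` composes the per-step linear-fractional
  maps (saturating pre-CLS steps, the CLS step with its downstream
  pseudo-first-order load, proportional post-CLS steps) into
  `A = V[Y0]/(1 + W[Y0])`.  The reduction is **division-free**: post-step
  binding denominators are cleared against the load structurally, so the
  same code runs on plain numbers and on the package's sparse-polynomial
  scalars, and the symbolic derivations below can never drift from the
  numeric forward model.

The truncation error of the closed form scales like the CLS margin
reported by `check_cls_conditions()`:
`min( q_c·X_c^T·(1+L), X_c^T / X_{c-1}^T )`, where `L` is the downstream
load.  The first term is the naive `q·X^T` smallness criterion inflated
by the load (every diverted downstream complex is also neglected in the
pre-CLS conservations); the second reflects that conservation caps the
neglected product sum at `X_c^T`.  Chains valid at margin `1e-3` agree
with the exact solve to well under 1%; the package default threshold
(0.01, two orders below 1) is the configurable reading of the asymptotic
`<<` conditions.

## Symbolic T/U derivation

For a (GR, cofactor) configuration the package builds a canonical
scaffold chain — a hidden saturating head step, pre-CLS slots, the
reporter-occupied CLS, post-CLS slots — with every parameter a symbol,
reduces it, substitutes the receptor occupancy `[GR] = G·S/(K+S)`, and
clears fractions.  The result is `A = T(S)/U(S)` with `T`, `U` of degree
one in `S` and in the cofactor amount `X`, and **positive composite
coefficients by construction** (all operations are additions and
multiplications of positive quantities).  The four dose-response
parameters follow as `Amax = T(0)/U(0)`, `Amin = T′/U′`,
`IC50 = U(0)/U′`, `Amax·IC50/Amin = T(0)/T′`, each linear-fractional in
`X`, and the four compatibility conditions (numerator of `Amax` ∝
numerator of the ratio, etc.) are verified as exact cancellation of
polynomial cross products — not as numeric near-equality.

Activity weights of post-CLS products are free positive symbols (the
first normalised to 1).  This matters: with the diverted branch's weight
fixed at zero, the ratio `Amax·IC50/Amin` would be exactly constant for
a receptor accelerator acting after the cofactor, whereas the general
form lets it decrease — which is the discriminating behaviour.

Coarse positions {before, at, after} relative to the CLS plus the
relative order of the two factors reproduce the published counting:
10 ordered distinct-step arrangements + 3 same-step arrangements
(one accelerator, one decelerator); GR as a decelerator is admissible in
all 13 and as an accelerator (repression by diversion to a less
productive branch) only after the CLS, in 5 — 18 configurations.  The
six decelerator subtypes are reported as a separate expanded count
(13·6 + 5 = 83) and never folded into the headline 18.

## Feasibility analysis and the rule table

`feasibility_scan()` asks whether a configuration can produce an
observed sign pattern of the four parameter plots.  Verdicts are dual:
analytic (hard-coded inequality logic for the six canonical cases of a
post-CLS accelerator cofactor) and stochastic (parameters drawn
log-uniform on `[1e-3, 1e3]`, the receptor scale `G` swept over
{1, 10, 100} because several cases need `G` large, partial
productivities uniform on (0, 1); a configuration is feasible if any
draw reproduces the pattern).  `Amax > Amin` is enforced on a strictly
positive cofactor grid — at the true zero of a through-origin
configuration both sides vanish and the comparison is degenerate.

The 22-entry prediction table ships as data
(`inst/extdata/table1_rules.json`) and is applied by `classify()`: every
entry whose plot property matches the signature fires, and the
intersection over a subtype-expanded configuration universe is reported.
The table lists sufficient conditions and is not complete; on noisy data
a slowly-varying trace read as "constant" can fire a constant-condition
entry that contradicts a direction entry, emptying the intersection.
The decisive analysis is therefore `infer_gr_action()`, which treats
"constant" observations as non-informative (a trendless cofactor neither
confirms nor contradicts) and intersects stochastic feasibility across
cofactors — exactly how the receptor position is pinned down from the
cofactor data.

## Signature extraction: robustness choices

Direction calls on fitted parameter plots are deliberately conservative;
a wrong decisive call poisons the feasibility intersection, while an
unnecessary "constant" merely widens it.

* A direction is called only when the flat shape loses by more than 2
  BIC *and* the fitted curve varies by more than a per-parameter
  relative range over the data: 25% for `Amax`/`Amin`, 40% for `IC50`,
  80% for the ratio.  `IC50` compounds two fitted quantities and the
  ratio three, and their small-sample estimator bias at four-dose
  designs is of exactly that order.
* Per-cell `IC50` estimates outside ten times the measured dose range
  are unidentifiable and reported `NA`; cells with fold repression below
  1.3 have no meaningful half-suppression point, so their `IC50` and
  ratio are also `NA`.  `NA` cells drop out of the averaged series.
* Half-max orderings from point fits are reported only when decisive
  (relative difference above 20%); exact equality is a posterior-level
  statement, available from `posterior_halfmax_ordering()` on MCMC
  chains.
* "Through the origin" combines the BIC preference for the
  linear-through-origin shape with the x-intercept lying within 2
  standard errors of minus the endogenous level; extrapolation to the
  true zero falls back to the nearest measured point when the fitted
  curve has a pole in between.

## The synthetic world

The generator's defaults emulate the factorial competition assay:
reporter doses {10, 35, 70, 140} ng, cofactor doses {0, 10, 30, 100}
(ng or µM), steroid {0, 3, 30, 300} nM, triplicates, four independent
experiments, multiplicative log-normal noise with 5% replicate CV and a
10% per-experiment scale jitter.  An endogenous cofactor offset of
2.7 ng-equivalents is used for protein cofactors (zero for small
molecules), so the true zero of total factor sits left of the nominal
dose axis.

Kinetic defaults (units arbitrary but consistent): inducer `Y0 = 10`
with a saturating head step (`q = 1`, pool 10); CLS affinity
`q_c = 0.05` acting on the reporter at a 2.5·10⁻⁴ concentration-per-ng
scale — the molar-scale separation that keeps `q_c·conc ≤ 0.01` over the
dose range while the post-CLS pools stay in excess; post-CLS accelerator
strengths of order one (`q·X` up to ~30); receptor scale `G = 10`,
steroid binding constant `K = 30` nM (placing true IC50s mid-grid),
receptor-step strengths giving several-fold repression; the diverted
post-receptor branch carries 3% of the productive branch's activity
weight ("much less productive").  Two structural rules keep one stated
world serving all 18 configurations: the head pool is enlarged to
compensate the attenuation of intermediate pre-CLS slots (the CLS load
term, which carries all post-CLS repression, keeps its scale), but only
up to the point where no intermediate step saturates in its input
(`q·[Y_in] ≤ 0.3`) — a decelerator acting on a saturated step would be
shielded.

What a green end-to-end test establishes: that the pipeline recovers the
generating (mechanism, position) configuration from data produced by the
theory's own forward model under realistic noise.  What it does not
establish: anything about real luciferase data (plate effects,
transfection-efficiency structure beyond a scalar jitter, deviations
from mass-action equilibrium, transcriptional bursting are all outside
the generator).

## MCMC and model comparison

The three model structures tie the four parameter equations together
exactly as the compatibility conditions dictate (predicted, 8
parameters), scramble the shared constants at equal complexity
(permuted, 8), or free them all (unconstrained, 12; the predicted model
is nested inside it).  The fourth equation of each triplet is the
combination `Amax·IC50/Amin` — the only reading consistent with the
compatibility structure.  Likelihood is `exp(-χ²/2)` with
`χ² = Σ (y-model)²/σ²` summed over the four series (the positive sum;
a likelihood cannot increase with misfit), `σ` the experimental SEM
floored at 2% of the series scale.  Sampling runs in log-parameter space
(positivity by construction, flat prior on the log box `[1e-4, 1e4]`),
with independent Gaussian proposals whose scales adapt toward 25%
acceptance during burn-in only and are then frozen, preserving detailed
balance for the retained samples.  `χ²_min` is the better of the chain
maximum and a Nelder-Mead refinement from it; the unconstrained model
additionally restarts from the embedded predicted optimum so the nesting
inequality holds up to optimiser tolerance.  `BIC = χ²_min + k·ln n`
with `n` the total number of data points.  Default test-scale chains run
2·10⁵ iterations (a hundredth of full scale; the unconstrained model
1.5× longer), which the Rcpp sampler covers in well under a second;
`--full-scale-mcmc` restores 2·10⁷.

## Numerical choices

* Equilibrium solve: log-concentration Newton with backtracking line
  search, three deterministic starts, relative residual `1e-10`.
* Two-stage dose-response fit: vehicle-well mean for the zero-dose
  plateau (fidelity to the published recipe; a joint three-parameter
  fit is available for comparison), then a profiled Michaelis-Menten
  stage — the amplitude is linear given the half-saturation, which is
  found on a coarse log grid plus golden-section polish because the
  profiled RSS can be multimodal on noisy four-point designs.
* Shape fits: weighted least squares with positivity on the canonical
  orientation `(a + bx)/(1 + dx)`; nested shapes constant, `b·x`,
  `a + bx`, `V·x/(m+x)` compared by `BIC = χ² + k·ln n`.
* "Constant" classification tolerance for the `ad` vs `bc` rule: 5%
  relative, configurable.
* Hill fits: four-parameter log-space optimisation (BFGS plus
  Nelder-Mead polish).

## Known limitations

* Multi-CLS chains are supported by the diagnostics and the numeric
  oracle, but the closed form requires all activity weights within one
  CLS block (otherwise the activity is a sum of linear-fractional
  functions and not itself linear-fractional).
* The rule-table intersection can be empty on noisy data (see above);
  it is reported as evidence, not used as the final call.
* Feasibility is established by stochastic witness search; absence of a
  witness at 10⁵ draws is strong but not a proof, except where the
  analytic case verdicts apply.
* The theory itself is an equilibrium mean-field description; kinetic
  time courses (beyond the irreversible-equivalence check) and
  stochastic transcription bursting are out of scope.
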