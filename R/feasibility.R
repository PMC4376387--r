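# Feasibility analysis: which (mechanism, position) configurations of GR
# and a cofactor can produce an observed qualitative sign pattern of the
# four dose-response-parameter plots.

#' Sign pattern of the four dose-response-parameter plots
#'
#' @param amax,amin,ic50,ratio Required direction of each plot versus the
#'   cofactor: `"inc"`, `"dec"`, `"const"` or `NA` (no requirement).
#' @param amax_gt_amin Whether `Amax > Amin` (actual repression) is
#'   required across the cofactor range.
#' @export
sign_pattern <- function(amax = NA, amin = NA, ic50 = NA, ratio = NA,
                         amax_gt_amin = TRUE) {
  ok <- function(x) is.na(x) || x %in% c("inc", "dec", "const")
  stopifnot(ok(amax), ok(amin), ok(ic50), ok(ratio))
  structure(list(amax = amax, amin = amin, ic50 = ic50, ratio = ratio,
                 amax_gt_amin = isTRUE(amax_gt_amin)),
            class = "sign_pattern")
}

#' The repression pattern observed for a TIF2-like coactivator
#'
#' `Amax` increases while `Amin`, `IC50` and `Amax*IC50/Amin` all decrease
#' with added cofactor, and `Amax > Amin`.
#' @export
tif2_pattern <- function() {
  sign_pattern("inc", "dec", "dec", "dec", amax_gt_amin = TRUE)
}

# draw positive parameter values for the free symbols of a form set:
# log-uniform over [lo, hi], except the receptor scale G (swept over a
# fixed grid because feasibility often needs G large), half-saturation K
# (log-uniform), and partial-productivity betas (uniform on (0,1))
sample_symbol_env <- function(symbols, n, G_values = c(1, 10, 100),
                              lo = 1e-3, hi = 1e3) {
  env <- vector("list", length(symbols))
  names(env) <- symbols
  for (s in symbols) {
    env[[s]] <- if (s == "G") {
      G_values[sample.int(length(G_values), n, replace = TRUE)]
    } else if (grepl("^beta", s)) {
      stats::runif(n)
    } else {
      exp(stats::runif(n, log(lo), log(hi)))
    }
  }
  env
}

# vectorised evaluation of the four forms over a parameter draw: returns
# a, b, c, d matrices (n x 4) keyed by parameter name
eval_forms_matrix <- function(forms, env) {
  out <- list()
  for (p in c("amax", "amin", "ic50", "ratio")) {
    lfs <- forms[[p]]
    out[[p]] <- list(a = kp_eval(lfs$a, env), b = kp_eval(lfs$b, env),
                     c = kp_eval(lfs$c, env), d = kp_eval(lfs$d, env))
  }
  out
}

# direction of each draw: "inc", "dec" or "const" by the ad vs bc rule
lf_direction_vec <- function(co, const_tol = 1e-9) {
  det <- co$a * co$d - co$b * co$c
  scale <- pmax(abs(co$a * co$d), abs(co$b * co$c), .Machine$double.xmin)
  ifelse(abs(det) <= const_tol * scale, "const", ifelse(det < 0, "inc", "dec"))
}

match_pattern_vec <- function(mats, pattern, x_grid) {
  n <- length(mats$amax$a)
  ok <- rep(TRUE, n)
  for (p in c("amax", "amin", "ic50", "ratio")) {
    want <- pattern[[p]]
    if (is.na(want)) next
    ok <- ok & (lf_direction_vec(mats[[p]]) == want)
  }
  if (pattern$amax_gt_amin) {
    for (x in x_grid) {
      vmax <- (mats$amax$a + mats$amax$b * x) / (mats$amax$c + mats$amax$d * x)
      vmin <- (mats$amin$a + mats$amin$b * x) / (mats$amin$c + mats$amin$d * x)
      ok <- ok & (vmax > vmin)
    }
  }
  ok
}

#' Scan a configuration for feasibility of a sign pattern
#'
#' Dual verdicts.  Stochastic: draw positive parameters (log-uniform over
#' `[1e-3, 1e3]`, receptor scale `G` swept over `G_values`), evaluate the
#' symbolically derived parameter forms and test the pattern; feasible if
#' any witness is found.  Analytic: hard-coded inequality logic for the
#' six canonical cases of a post-CLS accelerator cofactor versus the
#' repression pattern (`NA` when no analytic result is available).
#'
#' @param config A [configuration()].
#' @param pattern A [sign_pattern()].
#' @param n_samples Number of stochastic draws (`>= 1`).
#' @param seed RNG seed for reproducibility.
#' @param x_grid Cofactor amounts at which `Amax > Amin` is enforced
#'   (strictly positive: at a true zero of a through-origin configuration
#'   both vanish and the comparison is degenerate).
#' @param G_values Receptor-scale sweep.
#' @return List with `feasible` (stochastic), `analytic_verdict`
#'   (`TRUE`/`FALSE`/`NA`), `n_matching`, `witness` (named parameter list
#'   of the first matching draw, or `NULL`).
#' @export
feasibility_scan <- function(config, pattern, n_samples = 1e4, seed = 1,
                             x_grid = c(0.5, 2, 10, 50, 100),
                             G_values = c(1, 10, 100)) {
  stopifnot(inherits(config, "configuration"), inherits(pattern, "sign_pattern"))
  forms <- dr_param_forms(derive_TU(config))
  set.seed(seed)
  env <- sample_symbol_env(forms$symbols, n_samples, G_values = G_values)
  mats <- eval_forms_matrix(forms, env)
  ok <- match_pattern_vec(mats, pattern, x_grid)
  witness <- NULL
  if (any(ok)) {
    i <- which(ok)[1L]
    witness <- lapply(env, `[`, i)
  }
  list(feasible = any(ok),
       analytic_verdict = analytic_case_verdict(config, pattern),
       n_matching = sum(ok),
       witness = witness)
}

#' Analytic verdict for the six canonical GR-position cases
#'
#' For a cofactor acting as an accelerator after the CLS and the full
#' repression pattern (`Amax` up, `Amin`/`IC50`/ratio down, `Amax > Amin`),
#' the six distinct-step cases have closed verdicts: GR as decelerator
#' before or at the CLS forces a constant ratio (infeasible); GR as
#' accelerator after the CLS but before the cofactor makes `Amax`
#' independent of the cofactor (infeasible); GR as competitive decelerator
#' after the CLS but before the cofactor leads to contradictory
#' inequalities (infeasible); GR as accelerator after the cofactor is
#' feasible; GR as (gamma-binding) decelerator after the cofactor forces
#' `IC50` to increase (infeasible).  Everything else returns `NA`.
#'
#' @param config A [configuration()].
#' @param pattern A [sign_pattern()].
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
analytic_case_verdict <- function(config, pattern) {
  full <- tif2_pattern()
  same <- all(vapply(c("amax", "amin", "ic50", "ratio"), function(p) {
    identical(pattern[[p]], full[[p]])
  }, logical(1))) && pattern$amax_gt_amin
  if (!same) return(NA)
  if (config$factor_mech$kind != "A" || config$factor_pos != "after") return(NA)
  if (config$order == "same-step") return(NA)
  gk <- config$gr_mech$kind
  gt <- config$gr_mech$decel_type
  gamma_binding <- is.null(gt) || substr(gt, 2, 2) %in% c("C", "N")
  if (gk == "D" && config$gr_pos %in% c("before", "at")) return(FALSE)  # cases 1, 2
  if (gk == "A" && config$order == "GR-before-F") return(FALSE)        # case 3
  if (gk == "D" && config$gr_pos == "after" && config$order == "GR-before-F" &&
      gamma_binding) return(FALSE)                                     # case 4
  if (gk == "A" && config$order == "GR-after-F") return(TRUE)          # case 5
  if (gk == "D" && config$gr_pos == "after" && config$order == "GR-after-F" &&
      gamma_binding) return(FALSE)                                     # case 6
  NA
}

#' Localise GR by intersecting feasibility across cofactors
#'
#' For each cofactor's observed plot signature, every candidate
#' configuration is scanned for feasibility; configurations that survive
#' every cofactor form the conclusion set.  `"const"` directions are
#' treated as non-informative (matched against any direction), so a
#' trendless cofactor neither confirms nor contradicts — such cofactors
#' are flagged.
#'
#' @param signatures Named list: cofactor id -> [sign_pattern()] (or a
#'   `plot_signature` from [extract_signature()], which is converted).
#' @param configs Candidate configurations (default
#'   [enumerate_configurations()]).
#' @param n_samples,seed,G_values Passed to [feasibility_scan()].
#' @return List with `survivors` (named list of configurations),
#'   `feasibility` (logical matrix configs x cofactors),
#'   `uninformative` (cofactors whose row is all-feasible), and
#'   `diagnosis` (`"consistent"` or `"model-inconsistent"` when no
#'   configuration survives).
#' @export
infer_gr_action <- function(signatures, configs = enumerate_configurations(),
                            n_samples = 2e3, seed = 1, G_values = c(1, 10, 100)) {
  stopifnot(length(signatures) >= 1L)
  patterns <- lapply(signatures, as_sign_pattern)
  feas <- matrix(NA, nrow = length(configs), ncol = length(patterns),
                 dimnames = list(names(configs), names(patterns)))
  for (j in seq_along(patterns)) {
    # const observations are non-informative: drop the requirement
    pat <- patterns[[j]]
    for (p in c("amax", "amin", "ic50", "ratio")) {
      if (identical(pat[[p]], "const")) pat[[p]] <- NA
    }
    for (i in seq_along(configs)) {
      sc <- feasibility_scan(configs[[i]], pat, n_samples = n_samples,
                             seed = seed + i, G_values = G_values)
      feas[i, j] <- sc$feasible
    }
  }
  alive <- rowSums(feas) == ncol(feas)
  survivors <- configs[alive]
  list(survivors = survivors,
       feasibility = feas,
       uninformative = colnames(feas)[colSums(feas) == nrow(feas)],
       diagnosis = if (any(alive)) "consistent" else "model-inconsistent")
}

# accept sign_pattern as-is; convert a plot_signature (from
# extract_signature) into its direction pattern
as_sign_pattern <- function(x) {
  if (inherits(x, "sign_pattern")) return(x)
  if (inherits(x, "plot_signature")) {
    return(sign_pattern(x$direction[["amax"]], x$direction[["amin"]],
                        x$direction[["ic50"]], x$direction[["ratio"]],
                        amax_gt_amin = isTRUE(x$amax_gt_amin)))
  }
  stop("cannot interpret object as a sign pattern")
}
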