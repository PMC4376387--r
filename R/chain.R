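#' Reaction step of a gene-expression chain
#'
#' One complex-building reaction `Y[i-1] + X[i] <-> Y[i]` with equilibrium
#' (affinity) constant `q` and total accelerator concentration `X_total`.
#' Units are arbitrary but must be consistent across the chain (the assays
#' the model describes work in relative plasmid ng and normalised
#' luciferase units, so no unit layer is imposed).
#'
#' @param q Equilibrium/affinity constant (1/concentration), `> 0`.
#' @param X_total Total accelerator concentration, `>= 0`.
#' @return An object of class `reaction_step`.
#' @export
reaction_step <- function(q, X_total) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0,
            is.numeric(X_total), length(X_total) == 1L, X_total >= 0)
  structure(list(q = q, X_total = X_total), class = "reaction_step")
}

#' Equilibrium reaction chain with a concentration-limited step
#'
#' An ordered sequence of [reaction_step()]s driven by the inducer
#' concentration `[Y0]`.  One (or more) steps are flagged as the
#' concentration-limited step (CLS): the step whose accelerator is limited
#' with respect to its binding affinity while every following accelerator
#' is in excess.  Measured activity is a weighted sum of the product
#' concentrations at and after the CLS, `A = sum(w[i] * [Y[i]])`; by
#' default every such product gets weight 1 (each step after the CLS can
#' independently give rise to final product).  Setting later weights below
#' earlier ones makes a post-CLS accelerator divert flux to a less
#' productive branch, which is how an accelerator can repress.
#'
#' @param steps List of [reaction_step()] objects.
#' @param cls_index Integer step index (or indices) of the CLS.
#' @param inducer_conc Concentration of the initial product `[Y0]`.
#' @param activity_weights Named or positional numeric vector of weights
#'   `w[i]` for products `[Y[i]]`, `i >= min(cls_index)`.  `NULL` means
#'   weight 1 for the CLS product and everything after it.
#' @param include_cls_product Whether the CLS product itself contributes to
#'   activity (default `TRUE`, matching the worked three-reaction example
#'   where the sum starts at the CLS product).
#' @return An object of class `reaction_chain`.
#' @examples
#' ch <- reaction_chain(
#'   steps = list(reaction_step(1, 1), reaction_step(0.01, 1), reaction_step(1, 1)),
#'   cls_index = 2, inducer_conc = 1,
#'   activity_weights = c(0, 1)  # only [Y3] counts
#' )
#' closed_form_dose_response(ch)
#' @export
reaction_chain <- function(steps, cls_index, inducer_conc = 1,
                           activity_weights = NULL,
                           include_cls_product = TRUE) {
  stopifnot(length(steps) >= 1L, all(vapply(steps, inherits, TRUE, "reaction_step")))
  n <- length(steps)
  cls_index <- sort(unique(as.integer(cls_index)))
  if (any(cls_index < 1L) || any(cls_index > n)) {
    stop("cls_index must name steps of the chain (1..", n, ")")
  }
  stopifnot(is.numeric(inducer_conc), inducer_conc >= 0)
  first_weighted <- if (include_cls_product) min(cls_index) else min(cls_index) + 1L
  if (first_weighted > n) stop("no product at or after the CLS carries activity")
  n_w <- n - first_weighted + 1L
  if (is.null(activity_weights)) {
    activity_weights <- rep(1, n_w)
  }
  if (length(activity_weights) != n_w) {
    stop("activity_weights must have one weight per product from step ",
         first_weighted, " to ", n)
  }
  if (any(activity_weights < 0) || all(activity_weights == 0)) {
    stop("activity_weights must be >= 0 with at least one positive entry")
  }
  structure(list(steps = steps, cls_index = cls_index,
                 inducer_conc = inducer_conc,
                 activity_weights = activity_weights,
                 first_weighted = first_weighted),
            class = "reaction_chain")
}

#' @export
print.reaction_chain <- function(x, ...) {
  n <- length(x$steps)
  cat(sprintf("<reaction_chain> %d steps, CLS at %s, [Y0] = %g\n",
              n, paste(x$cls_index, collapse = ","), x$inducer_conc))
  for (i in seq_len(n)) {
    role <- if (i %in% x$cls_index) "CLS" else if (i < min(x$cls_index)) "pre" else "post"
    w <- if (i >= x$first_weighted) x$activity_weights[i - x$first_weighted + 1L] else NA
    cat(sprintf("  step %d: q = %g, X_total = %g  [%s]%s\n", i,
                x$steps[[i]]$q, x$steps[[i]]$X_total, role,
                if (!is.na(w)) sprintf("  w = %g", w) else ""))
  }
  invisible(x)
}

#' Decelerator (enzymatic-inhibitor-like factor) attached to a step
#'
#' A decelerator `D` inhibits reaction `step` by binding the accelerator
#' (affinity `gamma * q_prime`) and/or the nascent product (affinity
#' `alpha * q_prime`); the partially productive bound product re-enters the
#' chain with efficiency `beta`.  The six canonical types are
#' competitive (`alpha = 0`), uncompetitive (`gamma = 0`), noncompetitive
#' (`alpha = gamma`), each either linear (`beta = 0`) or partial
#' (`beta > 0`).  The free decelerator concentration is treated as a fixed
#' external parameter (decelerator in excess), so no conservation equation
#' is written for `D`.
#'
#' @param step Index of the inhibited reaction.
#' @param conc Free decelerator concentration `[D] >= 0`.
#' @param q_prime Affinity constant `q' > 0`.
#' @param alpha Product-binding strength (dimensionless multiplier, `>= 0`).
#' @param beta Partial productivity in `[0, 1]`.
#' @param gamma Accelerator-binding strength (`>= 0`).
#' @return An object of class `decelerator_spec` with a `type` field such
#'   as `"LC"` (linear competitive) or `"PN"` (partial noncompetitive).
#' @export
decelerator_spec <- function(step, conc, q_prime = 1, alpha = 0, beta = 0,
                             gamma = 1) {
  stopifnot(conc >= 0, q_prime > 0, alpha >= 0, beta >= 0, beta <= 1, gamma >= 0)
  if (alpha == 0 && gamma == 0) {
    stop("alpha and gamma cannot both be zero (the decelerator would bind nothing)")
  }
  structure(list(step = as.integer(step), conc = conc, q_prime = q_prime,
                 alpha = alpha, beta = beta, gamma = gamma,
                 type = decel_type_label(alpha, beta, gamma)),
            class = "decelerator_spec")
}

decel_type_label <- function(alpha, beta, gamma) {
  mech <- if (alpha == 0) "C" else if (gamma == 0) "U" else if (alpha == gamma) "N" else "M"
  paste0(if (beta == 0) "L" else "P", mech)
}

#' Canonical decelerator parameterisation from a two-letter type label
#'
#' @param type One of `"LC"`, `"LU"`, `"LN"`, `"PC"`, `"PU"`, `"PN"`.
#' @param step,conc,q_prime Passed to [decelerator_spec()].
#' @param strength Value used for the nonzero `alpha`/`gamma` multipliers.
#' @param beta Partial productivity used for the `P` types.
#' @export
decelerator_of_type <- function(type, step, conc, q_prime = 1, strength = 1,
                                beta = 0.5) {
  type <- toupper(type)
  stopifnot(type %in% c("LC", "LU", "LN", "PC", "PU", "PN"))
  b <- if (substr(type, 1, 1) == "P") beta else 0
  switch(substr(type, 2, 2),
    C = decelerator_spec(step, conc, q_prime, alpha = 0, beta = b, gamma = strength),
    U = decelerator_spec(step, conc, q_prime, alpha = strength, beta = b, gamma = 0),
    N = decelerator_spec(step, conc, q_prime, alpha = strength, beta = b, gamma = strength)
  )
}

#' Oligomerisation pre-step for an accelerator
#'
#' An accelerator `X` that first forms a hetero-oligomer with a
#' superabundant partner `Z` (`X + Z <-> XZ`, affinity `r`) before acting.
#'
#' @param r Oligomerisation affinity, `> 0`.
#' @param Z_total Superabundant partner concentration, `>= 0`.
#' @export
oligomer_spec <- function(r, Z_total) {
  stopifnot(r > 0, Z_total >= 0)
  structure(list(r = r, Z_total = Z_total), class = "oligomer_spec")
}

# ---------------------------------------------------------------------------
# JSON (de)serialisation of chain + decelerator specifications

#' Serialise a chain and its decelerators to JSON
#'
#' @param chain A [reaction_chain()].
#' @param decels Optional list of [decelerator_spec()] objects.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
chain_to_json <- function(chain, decels = list(), path = NULL) {
  obj <- list(
    steps = lapply(chain$steps, function(s) list(q = s$q, X_total = s$X_total)),
    cls_index = chain$cls_index,
    inducer_conc = chain$inducer_conc,
    activity_weights = chain$activity_weights,
    first_weighted = chain$first_weighted,
    decelerators = lapply(decels, function(d) {
      list(step = d$step, conc = d$conc, q_prime = d$q_prime,
           alpha = d$alpha, beta = d$beta, gamma = d$gamma)
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a chain (and decelerators) back from JSON
#'
#' @param path File path or JSON string produced by [chain_to_json()].
#' @return A list with elements `chain` and `decels`.
#' @export
chain_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  steps <- lapply(obj$steps, function(s) reaction_step(s$q, s$X_total))
  chain <- reaction_chain(steps, cls_index = unlist(obj$cls_index),
                          inducer_conc = obj$inducer_conc,
                          activity_weights = unlist(obj$activity_weights),
                          include_cls_product =
                            obj$first_weighted == min(unlist(obj$cls_index)))
  decels <- lapply(obj$decelerators, function(d) {
    decelerator_spec(d$step, d$conc, d$q_prime, d$alpha, d$beta, d$gamma)
  })
  list(chain = chain, decels = decels)
}
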