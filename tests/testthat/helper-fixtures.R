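# Shared fixtures: all built in code, nothing read from disk.

# the worked three-reaction induction chain: CLS at step 2, activity from
# the terminal product only
chain3 <- function(q2 = 0.01) {
  reaction_chain(
    list(reaction_step(1, 1), reaction_step(q2, 1), reaction_step(1, 1)),
    cls_index = 2, inducer_conc = 1, activity_weights = c(0, 1))
}

# a random chain guaranteed to satisfy the CLS regime at `threshold`:
# the CLS affinity is scaled down by the downstream load, and the CLS
# accelerator pool is kept small against the feed product
random_cls_chain <- function(threshold = 1e-3, n_post = 2) {
  q1 <- exp(stats::runif(1, -1, 1))
  x1 <- exp(stats::runif(1, 0, 2))
  y0 <- exp(stats::runif(1, -1, 1))
  post <- replicate(n_post, c(exp(stats::runif(1, -1, 1)),
                              exp(stats::runif(1, 0, 1))), simplify = FALSE)
  L <- 0; run <- 1
  for (p in post) { L <- L + run * p[1] * p[2]; run <- run * p[1] * p[2] }
  x2 <- threshold * stats::runif(1, 0.1, 0.9) *
    min(q1 * x1 * y0 / (1 + q1 * y0), 1)         # X_c^T << [Y1]
  qc <- threshold * stats::runif(1, 0.1, 0.9) / (x2 * (1 + L))
  steps <- c(list(reaction_step(q1, x1), reaction_step(qc, x2)),
             lapply(post, function(p) reaction_step(p[1], p[2])))
  reaction_chain(steps, cls_index = 2, inducer_conc = y0)
}

# evaluate the repression dose-response of Eq-1 type
eq1 <- function(S, amax, amin, ic50) (amax + amin * S / ic50) / (1 + S / ic50)

# canonical configurations used across tests
cfg_case <- function(case) {
  A <- mechanism("A"); LC <- mechanism("D", "LC")
  switch(as.character(case),
    "1" = configuration(A, "after", LC, "before", "GR-before-F"),
    "2" = configuration(A, "after", LC, "at", "GR-before-F"),
    "3" = configuration(A, "after", A, "after", "GR-before-F"),
    "4" = configuration(A, "after", LC, "after", "GR-before-F"),
    "5" = configuration(A, "after", A, "after", "GR-after-F"),
    "6" = configuration(A, "after", LC, "after", "GR-after-F"))
}

# hand-built signature with explicit feature values (defaults neutral)
mk_sig <- function(amax = "const", amin = "const", ic50 = "const",
                   ratio = "const", linear = c(FALSE, FALSE),
                   origin = c(FALSE, FALSE), pos0 = c(FALSE, FALSE),
                   zero_inf = c(FALSE, FALSE), ord = "unknown",
                   ord_inv = "unknown", gt = TRUE) {
  p <- c("amax", "amin", "ic50", "ratio")
  structure(list(
    direction = setNames(c(amax, amin, ic50, ratio), p),
    linear = setNames(c(linear, FALSE, FALSE), p),
    through_origin = setNames(c(origin, FALSE, FALSE), p),
    positive_at_true_zero = setNames(c(pos0, FALSE, FALSE), p),
    approaches_zero = setNames(c(zero_inf, FALSE, FALSE), p),
    ord_amin_amax = ord, ord_inv_amin_amax = ord_inv,
    half_max = setNames(rep(NA_real_, 4), p),
    reciprocal_half_max = setNames(rep(NA_real_, 4), p),
    amax_gt_amin = gt, endogenous_level = 0), class = "plot_signature")
}

# signature built directly from known linear-fractional shapes (bypasses
# the fitting stage); shapes is a named list of linear_fractional objects
signature_from_lfs <- function(shapes, endogenous = 0, amax_gt_amin = TRUE,
                               shape_names = NULL) {
  fits <- list()
  for (p in names(shapes)) {
    lf <- shapes[[p]]
    x <- c(0, 10, 30, 100) + endogenous
    y <- lf_eval(lf, x)
    fits[[p]] <- structure(list(
      shape = if (!is.null(shape_names[[p]])) shape_names[[p]] else "lf",
      lf = lf, coef = c(a = lf$a, b = lf$b, d = lf$d),
      chi2 = c(const = 100, lf = 0),
      bic = c(const = 100, lf = 4), k = 3, n = 4,
      x_intercept = if (lf$b != 0) -lf$a / lf$b else NA_real_,
      x_intercept_se = 1e-6,
      x = x, y = y, sem = rep(0.01, 4)), class = "param_fit")
  }
  extract_signature(fits, endogenous_level = endogenous,
                    amax_gt_amin = amax_gt_amin)
}
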