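# Dose-response fitting, grid normalisation, Western linearisation and
# parameter-plot shape fitting.

test_that("two-stage fit is exact on noiseless Eq-1 data", {
  s <- c(0, 10, 100, 1000)
  a <- eq1(s, 100, 20, 50)
  expect_equal(a, c(100, 100 / 1.2 + 20 * 10 / 50 / 1.2, 140 / 3, 500 / 21),
               tolerance = 1e-9)
  est <- fit_dose_response(s, a)
  expect_equal(est$amax, 100, tolerance = 1e-6)
  expect_equal(est$amin, 20, tolerance = 1e-6)
  expect_equal(est$ic50, 50, tolerance = 1e-6)
  expect_equal(est$ratio, 100 * 50 / 20, tolerance = 1e-5)
  expect_gt(est$r_squared, 1 - 1e-10)
  # round trip over random parameter sets
  set.seed(31)
  for (i in 1:10) {
    amax <- exp(runif(1, 0, 3)); amin <- amax * runif(1, 0.05, 0.7)
    ic50 <- exp(runif(1, 2, 4.5))
    s_i <- c(0, ic50 * c(0.2, 1, 5))
    est_i <- fit_dose_response(s_i, eq1(s_i, amax, amin, ic50))
    expect_equal(est_i$amax, amax, tolerance = 1e-6)
    expect_equal(est_i$amin, amin, tolerance = 1e-4)
    expect_equal(est_i$ic50, ic50, tolerance = 1e-4)
  }
})

test_that("degenerate inputs are flagged, not fitted", {
  s <- c(0, 10, 100, 1000)
  flat <- fit_dose_response(s, rep(7, 4))
  expect_true(flat$flags$flat)
  expect_equal(flat$amax, flat$amin)
  expect_true(is.na(flat$ic50))

  rising <- fit_dose_response(s, c(10, 20, 40, 80))
  expect_true(rising$flags$wrong_mode)
  expect_error(fit_dose_response(c(1, 10, 100, 1000), rep(1, 4)), "zero-dose")
  expect_error(fit_dose_response(c(0, 10, 10, 10), rep(1, 4)), "positive doses")
})

test_that("midpoint identity: A(IC50) = (Amax + Amin)/2", {
  expect_equal(eq1(50, 100, 20, 50), 60)
})

test_that("median IC50 recovery within 15% at 5% CV (seeded study)", {
  set.seed(99)
  s <- rep(c(0, 10, 50, 250), each = 3)
  err <- replicate(200, {
    a <- eq1(s, 100, 20, 50) * exp(rnorm(length(s), 0, sqrt(log(1.0025))))
    fit_dose_response(s, a)$ic50
  })
  expect_lt(abs(stats::median(err, na.rm = TRUE) - 50) / 50, 0.15)
})

test_that("induction mode fits EC50", {
  s <- c(0, 10, 100, 1000)
  a <- (20 + 100 * s / 50) / (1 + s / 50)
  est <- fit_dose_response(s, a, mode = "induction")
  expect_equal(est$amin, 20, tolerance = 1e-6)
  expect_equal(est$amax, 100, tolerance = 1e-4)
  expect_equal(est$ec50, 50, tolerance = 1e-4)
})

test_that("grid normalisation anchors, averages and propagates SEM", {
  cfg <- cfg_case(5)
  truth <- ground_truth(cfg, endogenous = 2.7)
  tab <- generate_assay(truth, assay_design(n_experiments = 2),
                        noise_model(0, 0), seed = 1)
  ds <- normalize_grid(tab)
  anchor <- ds[ds$x == 0 & ds$group == min(ds$group), ]
  expect_equal(anchor$value, rep(1, nrow(anchor)), tolerance = 1e-9)
  # identical experiments: zero SEM everywhere
  expect_true(all(ds$sem < 1e-12 | !is.finite(ds$sem) | ds$n == 1))
  # noiseless normalised Amax equals the forward-model ratio series
  for (g in unique(ds$group)) {
    sub <- ds[ds$param == "amax" & ds$group == g, ]
    truth_series <- vapply(sub$x, function(x) {
      truth_activity(truth, g, x + 2.7, 0)
    }, numeric(1))
    anchor_truth <- truth_activity(truth, min(ds$group), 2.7, 0)
    expect_equal(sub$value, truth_series / anchor_truth, tolerance = 1e-9)
  }
  # re-normalising by the anchor is the identity (already 1)
  expect_equal(ds$value / ds$value[ds$param == "amax" & ds$x == 0 &
                                     ds$group == min(ds$group)][1],
               ds$value, tolerance = 1e-12)
  drop_anchor <- !(tab$cofactor_dose == min(tab$cofactor_dose) &
                     tab$reporter_dose == min(tab$reporter_dose))
  expect_error(normalize_grid(tab[drop_anchor, ]), "anchor")
})

test_that("western linearisation recovers the saturation constant", {
  p <- c(10, 25, 50, 100, 200)
  od <- 10 * p / (50 + p)
  expect_equal(od, c(10 / 6, 10 / 3, 5, 20 / 3, 8), tolerance = 1e-12)
  w <- western_linearize(od, p)
  expect_equal(w$calibration$m2, 50, tolerance = 1e-4)
  expect_equal(w$corrected_plasmid[p == 50], 25, tolerance = 1e-3)
  # linear regime: correction is nearly the identity
  expect_equal(w$corrected_plasmid[1] / p[1], 50 / 60, tolerance = 1e-3)
  # noisy recovery within 10% at 5% CV
  tab <- generate_western(list(m1 = 10, m2 = 50), p, cv = 0.05, seed = 2)
  w2 <- western_linearize(tab$od, tab$plasmid_ng)
  expect_lt(abs(w2$calibration$m2 - 50) / 50, 0.10)
  # no curvature: identity correction with a warning
  expect_warning(w3 <- western_linearize(0.01 * p, p), "identity")
  expect_equal(w3$corrected_plasmid, p)
})

test_that("shape fitting prefers the generating shape by BIC", {
  set.seed(15)
  x <- c(2.7, 12.7, 32.7, 102.7)
  # exactly linear through the origin beats Michaelis-Menten
  y_lin <- 0.05 * x * (1 + rnorm(4, 0, 0.01))
  f_lin <- fit_param_vs_cofactor(x, y_lin, sem = 0.01 * 0.05 * x)
  expect_lt(f_lin$bic["linear_origin"], f_lin$bic["mm"])
  expect_identical(f_lin$shape, "linear_origin")
  # a known linear-fractional is recovered within 5% at 1% noise
  truth_lf <- linear_fractional(2, 0.9, 1, 0.05)
  xs <- c(1, 4, 10, 25, 60, 120)
  y <- lf_eval(truth_lf, xs) * (1 + rnorm(length(xs), 0, 0.01))
  f <- fit_param_vs_cofactor(xs, y, sem = 0.01 * abs(y))
  expect_equal(unname(f$coef["a"]), 2, tolerance = 0.05)
  expect_equal(unname(f$coef["b"]), 0.9, tolerance = 0.05)
  expect_equal(unname(f$coef["d"]), 0.05, tolerance = 0.2)
  # x-axis intersection of the numerator, with its sign
  f2 <- fit_param_vs_cofactor(x, 1 + 0.1 * x, sem = rep(0.02, 4))
  expect_lt(f2$x_intercept, 0)
  expect_equal(f2$x_intercept, -10, tolerance = 0.05)
})

test_that("signatures read the canonical shape patterns", {
  # repression pattern of a post-CLS coactivator with the receptor after it
  sig <- signature_from_lfs(list(
    amax = linear_fractional(4, 1, 1, 0.05, canonical = FALSE),
    amin = linear_fractional(2, 0.2, 1, 0.4, canonical = FALSE),
    ic50 = linear_fractional(30, 1, 1, 0.2, canonical = FALSE),
    ratio = linear_fractional(50, 1, 1, 0.3, canonical = FALSE)),
    endogenous = 2.7)
  expect_identical(unname(sig$direction), c("inc", "dec", "dec", "dec"))
  expect_identical(sig$ord_amin_amax, "<")   # 2.5 < 20 (half-max c/d)
  expect_true(sig$positive_at_true_zero[["amax"]])

  # reporter-axis pattern: Amax linear through origin, IC50 constant
  sig2 <- signature_from_lfs(list(
    amax = linear_fractional(0, 0.1, 1, 0, canonical = FALSE),
    amin = linear_fractional(0, 0.02, 1, 0, canonical = FALSE),
    ic50 = linear_fractional(5, 0, 1, 0, canonical = FALSE),
    ratio = linear_fractional(25, 0, 1, 0, canonical = FALSE)),
    shape_names = list(amax = "linear_origin", amin = "linear_origin",
                       ic50 = "const", ratio = "const"))
  expect_identical(unname(sig2$direction["amax"]), "inc")
  expect_true(sig2$through_origin[["amax"]])
  expect_true(sig2$linear[["amax"]])
  expect_identical(unname(sig2$direction["ic50"]), "const")

  # all-flat series
  sig3 <- signature_from_lfs(list(
    amax = linear_fractional(2, 0, 1, 0, canonical = FALSE),
    amin = linear_fractional(1, 0, 1, 0, canonical = FALSE),
    ic50 = linear_fractional(5, 0, 1, 0, canonical = FALSE),
    ratio = linear_fractional(10, 0, 1, 0, canonical = FALSE)),
    shape_names = list(amax = "const", amin = "const", ic50 = "const",
                       ratio = "const"))
  expect_true(all(sig3$direction == "const"))
})
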