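# Forward model: exact equilibrium oracle, closed-form reduction, CLS
# diagnostics, Hill fits, irreversible-scheme equivalence, oligomers.

test_that("exact equilibrium solves the symmetric one-step case", {
  ch <- reaction_chain(list(reaction_step(1, 1)), cls_index = 1,
                       inducer_conc = 1)
  eq <- solve_equilibrium_numeric(ch)
  # Y1 = q X Y0 with X + Y1 = 1: Y1 = (1 - Y1) => Y1 = X = 1/2
  expect_equal(eq$Y, 0.5, tolerance = 1e-9)
  expect_equal(eq$X, 0.5, tolerance = 1e-9)
  expect_lt(eq$residual, 1e-10)
})

test_that("zero inducer gives empty products and free accelerators", {
  ch <- chain3()
  eq <- solve_equilibrium_numeric(ch, y0 = 0)
  expect_equal(eq$Y, rep(0, 3))
  expect_equal(eq$X, c(1, 1, 1))
})

test_that("closed form matches the printed three-reaction formulas", {
  cf <- closed_form_dose_response(chain3())
  expect_equal(attr(cf, "Amax"), 0.01 / 1.02, tolerance = 1e-12)
  expect_equal(attr(cf, "EC50"), 1 / 1.02, tolerance = 1e-12)
})

test_that("closed form tracks the exact equilibrium at its truncation order", {
  # the CLS truncation error scales with q2*X2T; at q2 = 1e-2 it is ~1.5e-2
  eq <- solve_equilibrium_numeric(chain3(1e-2))
  a <- lf_eval(closed_form_dose_response(chain3(1e-2)), 1)
  expect_equal(eq$activity, a, tolerance = 2e-2)
  # and tightens with the regime: q2 = 1e-3 agrees to 1e-2 (and better)
  eq2 <- solve_equilibrium_numeric(chain3(1e-3))
  a2 <- lf_eval(closed_form_dose_response(chain3(1e-3)), 1)
  expect_equal(eq2$activity, a2, tolerance = 2e-3)
})

test_that("oracle equivalence holds across random CLS-valid chains", {
  set.seed(11)
  for (i in 1:8) {
    ch <- random_cls_chain(threshold = 1e-3)
    expect_true(attr(check_cls_conditions(ch, threshold = 1e-3), "valid"))
    cf <- closed_form_dose_response(ch)
    for (y0 in 10^seq(-2, 2, length.out = 5)) {
      eq <- solve_equilibrium_numeric(ch, y0 = y0)
      expect_lt(abs(lf_eval(cf, y0) - eq$activity) / eq$activity, 1e-2)
    }
  }
})

test_that("competitive decelerator rescales EC50 but not Amax", {
  base <- closed_form_dose_response(chain3())
  d <- decelerator_spec(1, conc = 1, q_prime = 1, alpha = 0, beta = 0, gamma = 1)
  mod <- closed_form_dose_response(chain3(), list(d))
  expect_equal(attr(mod, "Amax"), attr(base, "Amax"), tolerance = 1e-12)
  expect_equal(attr(mod, "EC50") / attr(base, "EC50"), 2, tolerance = 1e-12)
})

test_that("linear decelerators only ever lower activity", {
  # partial (beta > 0) uncompetitive decelerators can raise output in this
  # equilibrium scheme (the productive bound complex adds to a product
  # pool pinned by equilibrium), so strict monotonicity is a property of
  # the linear types
  set.seed(3)
  types <- c("LC", "LU", "LN")
  for (i in 1:30) {
    ch <- random_cls_chain()
    step <- sample(length(ch$steps), 1)
    d <- decelerator_of_type(sample(types, 1), step,
                             conc = exp(runif(1, -1, 2)),
                             q_prime = exp(runif(1, -1, 1)),
                             strength = exp(runif(1, -1, 1)),
                             beta = runif(1))
    base <- closed_form_dose_response(ch)
    mod <- closed_form_dose_response(ch, list(d))
    for (y0 in c(0.01, 0.3, 1, 10, 300)) {
      expect_lte(lf_eval(mod, y0), lf_eval(base, y0) + 1e-12)
    }
  }
})

test_that("a partial uncompetitive decelerator can raise activity", {
  ch <- chain3(1e-3)
  d <- decelerator_of_type("PU", 3, conc = 2, q_prime = 1, strength = 1,
                           beta = 0.5)
  base <- lf_eval(closed_form_dose_response(ch), 1)
  mod <- lf_eval(closed_form_dose_response(ch, list(d)), 1)
  expect_gt(mod, base)
})

test_that("a diverting post-CLS accelerator strictly decreases activity", {
  mk <- function(x4) {
    reaction_chain(list(reaction_step(1, 1), reaction_step(1e-3, 1),
                        reaction_step(1, 1), reaction_step(0.5, x4)),
                   cls_index = 2, inducer_conc = 1,
                   activity_weights = c(1, 1, 0))
  }
  acts <- vapply(c(0, 0.5, 2, 10), function(x4) {
    lf_eval(closed_form_dose_response(mk(x4)), 1)
  }, numeric(1))
  expect_true(all(diff(acts) < 0))
})

test_that("CLS diagnostics classify and flag as expected", {
  ok <- reaction_chain(list(reaction_step(1, 1), reaction_step(1e-4, 1),
                            reaction_step(1, 1)), cls_index = 2)
  rep_ok <- check_cls_conditions(ok)
  expect_identical(rep_ok$role, c("pre", "cls", "post"))
  expect_true(attr(rep_ok, "valid"))

  bad <- reaction_chain(list(reaction_step(1, 1), reaction_step(1, 1),
                             reaction_step(1, 1)), cls_index = 2)
  rep_bad <- check_cls_conditions(bad)
  expect_false(attr(rep_bad, "valid"))
  expect_false(rep_bad$valid[2])

  # two-CLS chain: blocks are interleaved post/pre between the CLS steps
  two <- reaction_chain(list(reaction_step(1, 1), reaction_step(1e-4, 1),
                             reaction_step(1, 1), reaction_step(1e-3, 0.5),
                             reaction_step(1e-4, 1), reaction_step(2, 1)),
                        cls_index = c(2, 5))
  rep2 <- check_cls_conditions(two)
  expect_identical(rep2$role, c("pre", "cls", "post", "pre", "cls", "post"))
  expect_true(attr(rep2, "valid"))
})

test_that("hill fit recovers known exponents", {
  s <- c(0, 1, 3, 10, 30, 100, 300)
  h1 <- hill_fit(s, 5 * s / (10 + s))
  expect_equal(h1$hill_coefficient, 1, tolerance = 1e-5)
  expect_equal(h1$half_max_conc, 10, tolerance = 1e-4)

  h2 <- hill_fit(s, 5 * s^2 / (100 + s^2))
  expect_equal(h2$hill_coefficient, 2, tolerance = 1e-2)

  hf <- hill_fit(s, rep(2, length(s)))
  expect_true(hf$flat)
  expect_true(is.na(hf$hill_coefficient))
})

test_that("CLS-valid forward models have unit Hill coefficient", {
  set.seed(21)
  for (i in 1:5) {
    ch <- random_cls_chain()
    cf <- closed_form_dose_response(ch)
    ec50 <- attr(cf, "EC50")
    s <- c(0, ec50 * 10^seq(-2, 2, length.out = 9))
    h <- hill_fit(s, lf_eval(cf, s))
    expect_true(abs(h$hill_coefficient - 1) <= 0.01)
  }
})

test_that("hit-and-run steady states match the equivalent reversible forms", {
  v <- hit_and_run_steady_state("post-CLS-like", kf = 2, kr = 1,
                                totals = list(P_total = 1, X_total = 3))
  expect_equal(v, 6 / 7, tolerance = 1e-6)

  # kr large: the modified product relaxes instantly
  v0 <- hit_and_run_steady_state("post-CLS-like", kf = 1, kr = 1e6,
                                 totals = list(P_total = 1, X_total = 1))
  expect_lt(v0, 1e-5)

  # CLS-like with diverting partner, against q XT P / (1 + qP + q q' UT P)
  v1 <- hit_and_run_steady_state("CLS-like", kf = 2, kr = 1,
                                 totals = list(X_total = 3, U_total = 0.5,
                                               kf2 = 1, kr2 = 1),
                                 upstream_conc = 1)
  expect_equal(v1, 2 * 3 / (1 + 2 + 2 * 0.5), tolerance = 1e-5)
  # and the q' U = 0 reduction
  v2 <- hit_and_run_steady_state("CLS-like", kf = 2, kr = 1,
                                 totals = list(X_total = 3), upstream_conc = 1)
  expect_equal(v2, 2 * 3 / (1 + 2), tolerance = 1e-5)
  expect_error(hit_and_run_steady_state("CLS-like", kf = -1, kr = 1,
                                        totals = list(X_total = 1)))
})

test_that("oligomer-mediated steps saturate in the partner", {
  og <- oligomer_spec(1, 1)
  expect_equal(oligomer_effective_step(og, 1, 1, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(oligomer_effective_step(oligomer_spec(1, 0), 1, 1, 1), 0)
  # r[Z] -> Inf reduces to the plain accelerator step
  plain <- 1 * 1 * 1 / (1 + 1 * 1)
  big <- oligomer_effective_step(oligomer_spec(1, 1e8), 1, 1, 1)
  expect_equal(big, plain, tolerance = 1e-6)
  # monotone increasing in Z
  vals <- vapply(c(0.1, 0.5, 1, 5, 50), function(z) {
    oligomer_effective_step(oligomer_spec(1, z), 1, 1, 1)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("chain specifications round-trip through JSON", {
  ch <- chain3()
  d <- list(decelerator_of_type("PN", 1, conc = 2, q_prime = 0.5, beta = 0.25))
  txt <- chain_to_json(ch, d)
  back <- chain_from_json(txt)
  expect_equal(back$chain$activity_weights, ch$activity_weights)
  expect_equal(back$chain$cls_index, ch$cls_index)
  expect_equal(back$decels[[1]]$beta, 0.25)
  a1 <- lf_eval(closed_form_dose_response(ch, d), 1)
  a2 <- lf_eval(closed_form_dose_response(back$chain, back$decels), 1)
  expect_equal(a1, a2, tolerance = 1e-12)
})
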