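# Metropolis-Hastings fitting and BIC comparison of the three model
# structures.

truth_pred <- c(10, 20, 1, 5, 2, 0.5, 8, 3)

make_data <- function(model = "predicted", cv = 0.04, seed = 2) {
  generate_param_plots(model, truth_pred, cv = cv, n_experiments = 5,
                       seed = seed)
}

test_that("model structures expose the stated parameter counts", {
  expect_equal(model_spec("predicted")$k, 8)
  expect_equal(model_spec("permuted")$k, 8)
  expect_equal(model_spec("unconstrained")$k, 12)
})

test_that("chi-squared is the standardised residual sum", {
  dat <- as_mcmc_data(make_data(cv = 0))
  ms <- model_spec("predicted")
  # noiseless data at the generating parameters: chi2 = 0
  expect_lt(chi_squared(ms, truth_pred, dat), 1e-15)
  # a single 2-sigma residual contributes 4
  dat2 <- dat
  dat2$y[1, 1] <- dat2$y[1, 1] + 2 * dat2$s[1, 1]
  expect_equal(chi_squared(ms, truth_pred, dat2), 4, tolerance = 1e-9)
  # perturbing any parameter strictly increases chi2
  for (j in 1:8) {
    p2 <- truth_pred; p2[j] <- p2[j] * 1.3
    expect_gt(chi_squared(ms, p2, dat), 0)
  }
  # R and C++ evaluators agree
  expect_equal(chi_squared(ms, truth_pred, dat2),
               clskinetics:::chi2_cpp(ms$code, truth_pred, dat2$x, dat2$r,
                                      dat2$y, dat2$s),
               tolerance = 1e-10)
  # scaling residuals and sigmas jointly leaves chi2 unchanged
  dat3 <- dat2
  dat3$y <- dat3$y * 10
  dat3$s <- dat3$s * 10
  p3 <- truth_pred * c(1, 1, 1, 1, 10, 10, 10, 10)
  expect_equal(chi_squared(ms, p3, dat3), chi_squared(ms, truth_pred, dat2),
               tolerance = 1e-9)
})

test_that("BIC arithmetic", {
  expect_equal(10 + 8 * log(16), 32.18071, tolerance = 1e-5)
})

test_that("sampler is seeded-deterministic and calibrated on a Gaussian", {
  dat <- as_mcmc_data(make_data())
  ms <- model_spec("predicted")
  ch1 <- mh_sample(ms, dat, iterations = 2e4, seed = 11)
  ch2 <- mh_sample(ms, dat, iterations = 2e4, seed = 11)
  expect_identical(ch1$samples, ch2$samples)
  expect_gt(ch1$acceptance_rate, 0.05)
  expect_lt(ch1$acceptance_rate, 0.8)

  # conjugate check: a quadratic chi2 in one parameter gives a posterior
  # centred on the truth within Monte-Carlo error
  dat1 <- list(x = 0, r = 1, y = matrix(c(5, 1, 1, 1), 1),
               s = matrix(c(0.5, 1e6, 1e6, 1e6), 1), n_points = 4)
  # only the amax equation is informative: a5 * (a1+0)/(a2+0) ~ N(5, 0.5)
  ch <- mh_sample(ms, dat1, iterations = 1e5, seed = 3)
  pred <- exp(ch$samples[, "a5"]) * exp(ch$samples[, "a1"]) /
    exp(ch$samples[, "a2"])
  expect_lt(abs(mean(pred) - 5), 3 * stats::sd(pred) / sqrt(100))
})

test_that("posterior recovers the generating parameters", {
  dat <- as_mcmc_data(make_data())
  ch <- mh_sample(model_spec("predicted"), dat, iterations = 2e5, seed = 11)
  post_mean <- exp(colMeans(ch$samples))
  post_sd <- apply(exp(ch$samples), 2, stats::sd)
  ok <- abs(post_mean - truth_pred) <= 2 * post_sd
  expect_gte(sum(ok), 7)
})

test_that("model comparison ranks the generating structure first", {
  mc <- model_compare(make_data(seed = 5), iterations = 2e4, seed = 5)
  expect_identical(mc$best, "predicted")
  # BIC identity recomputed independently for every report
  for (rep in mc$reports) {
    expect_equal(rep$bic, rep$chi2_min + rep$k * log(rep$n), tolerance = 1e-9)
  }
  # nesting: the unconstrained fit is at least as good as the predicted
  tab <- mc$table
  expect_lte(tab$chi2_min[tab$model == "unconstrained"],
             tab$chi2_min[tab$model == "predicted"] + 1e-6)

  # permuted-truth data prefer the permuted structure
  dsp <- generate_param_plots("permuted", truth_pred, cv = 0.04,
                              n_experiments = 5, seed = 3)
  mcp <- model_compare(dsp, iterations = 2e4, seed = 6)
  expect_identical(mcp$best, "permuted")
  tabp <- mcp$table
  expect_gt(tabp$chi2_min[tabp$model == "predicted"],
            tabp$chi2_min[tabp$model == "permuted"])
})

test_that("whole model_compare pipeline is seeded-deterministic", {
  ds <- make_data(seed = 9)
  mc1 <- model_compare(ds, iterations = 5e3, seed = 4)
  mc2 <- model_compare(ds, iterations = 5e3, seed = 4)
  expect_identical(mc1$table, mc2$table)
})

test_that("half-max ordering probabilities read the posterior", {
  dat <- as_mcmc_data(make_data())
  ch <- mh_sample(model_spec("predicted"), dat, iterations = 2e5, seed = 11)
  # truth: a2 = 20 > a4 = 5 and a1 = 10 > a3 = 1
  p <- posterior_halfmax_ordering(ch)
  expect_gt(p[["a2>a4"]], 0.95)
  expect_gt(p[["a1>a3"]], 0.95)
  rh <- split_rhat(ch)
  expect_true(all(rh < 1.2, na.rm = TRUE))

  # symmetric truth: probability near 1/2
  tr_eq <- c(10, 20, 10, 20, 2, 2, 8, 1)
  ds_eq <- generate_param_plots("predicted", tr_eq, cv = 0.04,
                                n_experiments = 5, seed = 8)
  ch_eq <- mh_sample(model_spec("predicted"), as_mcmc_data(ds_eq),
                     iterations = 2e5, seed = 12)
  p_eq <- suppressWarnings(posterior_halfmax_ordering(ch_eq, list(c("a1", "a3"))))
  expect_gt(p_eq[[1]], 0.15)
  expect_lt(p_eq[[1]], 0.85)
})
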