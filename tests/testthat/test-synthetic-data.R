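# Synthetic competition-assay generator: noiseless round trips, ground
# truth sidecars, noise calibration.

test_that("noiseless assays reproduce the analytic dose-response exactly", {
  truth <- ground_truth(cfg_case(5), endogenous = 2.7)
  des <- assay_design(n_experiments = 1)
  tab <- generate_assay(truth, des, noise_model(0, 0), seed = 1)
  expect_s3_class(attr(tab, "truth"), "ground_truth")
  for (r in c(35, 140)) {
    for (xd in c(0, 30)) {
      sub <- tab[tab$reporter_dose == r & tab$cofactor_dose == xd, ]
      est <- fit_dose_response(sub$steroid_dose, sub$activity)
      amax_t <- truth_activity(truth, r, xd + 2.7, 0)
      amin_t <- truth_activity(truth, r, xd + 2.7, 1e12)
      expect_equal(est$amax, amax_t, tolerance = 1e-6)
      expect_equal(est$amin, amin_t, tolerance = 1e-3)
    }
  }
})

test_that("zero receptor scale removes all steroid dependence", {
  truth <- ground_truth(cfg_case(5), overrides = list(G = 0), endogenous = 2.7)
  tab <- generate_assay(truth, assay_design(n_experiments = 1),
                        noise_model(0, 0), seed = 1)
  for (cell in split(tab, list(tab$reporter_dose, tab$cofactor_dose))) {
    expect_lt(diff(range(cell$activity)) / mean(cell$activity), 1e-12)
  }
})

test_that("a TIF2-like truth produces the expected qualitative surface", {
  truth <- ground_truth(cfg_case(5), endogenous = 2.7)
  x_tot <- c(2.7, 12.7, 32.7, 102.7)
  amax <- vapply(x_tot, function(x) truth_activity(truth, 35, x, 0), 1)
  amin <- vapply(x_tot, function(x) truth_activity(truth, 35, x, 1e12), 1)
  expect_true(all(diff(amax) > 0))
  expect_true(all(diff(amin) < 0))
  expect_true(all(amax > amin))
})

test_that("replicate noise calibrates to the configured CV", {
  truth <- ground_truth(cfg_case(5), endogenous = 2.7)
  des <- assay_design(reporter_doses = 35, cofactor_doses = 30,
                      steroid_doses = c(0, 3, 30, 300),
                      replicates = 300, n_experiments = 1)
  tab <- generate_assay(truth, des, noise_model(0.05, 0), seed = 4)
  cvs <- vapply(split(tab, tab$steroid_dose), function(cell) {
    stats::sd(cell$activity) / mean(cell$activity)
  }, numeric(1))
  expect_true(all(abs(cvs - 0.05) / 0.05 < 0.2))
})

test_that("model-generated parameter plots behave as constructed", {
  p <- c(10, 20, 1, 5, 2, 0.5, 8, 3)
  ds0 <- generate_param_plots("predicted", p, cv = 0, n_experiments = 2,
                              seed = 1)
  # compatibility holds on the generating curves by construction
  x <- unique(ds0$x)
  amax <- ds0$value[ds0$param == "amax"]
  ratio <- ds0$value[ds0$param == "ratio"]
  # both share the numerator constant a1: amax*(a2+x) and ratio*(a3+x)
  # proportional to (a1+x)
  expect_equal(amax * (p[2] + x) / p[5], ratio * (p[3] + x) / p[8],
               tolerance = 1e-9)
  # sigma -> 0: the generating model achieves chi2 ~ 0
  dat0 <- as_mcmc_data(ds0)
  expect_lt(chi_squared(model_spec("predicted"), p, dat0), 1e-10)
})

test_that("the western generator saturates as specified", {
  tab <- generate_western(list(m1 = 10, m2 = 50),
                          plasmid = c(0, 10, 25, 50, 100, 200, 1e5), cv = 0,
                          seed = 1)
  expect_equal(tab$od[tab$plasmid_ng == 0], 0)
  expect_equal(tab$od[tab$plasmid_ng == 50], 5)
  expect_equal(tab$od[tab$plasmid_ng == 1e5], 10, tolerance = 1e-3)
})

test_that("assay generation is reproducible by seed", {
  truth <- ground_truth(cfg_case(5))
  t1 <- generate_assay(truth, assay_design(n_experiments = 1),
                       noise_model(), seed = 6)
  t2 <- generate_assay(truth, assay_design(n_experiments = 1),
                       noise_model(), seed = 6)
  expect_identical(t1$activity, t2$activity)
})

test_that("ground truths keep the CLS regime valid over the dose grids", {
  for (cfg in enumerate_configurations()) {
    truth <- ground_truth(cfg, endogenous = 2.7)
    tc <- truth_chain(truth, 140, 102.7, 300)
    rep <- check_cls_conditions(tc$chain, tc$decels)
    expect_true(attr(rep, "valid"))
  }
})
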