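# Rule-table engine and the feasibility analysis that localises GR.

test_that("all 22 rule entries are encoded", {
  rules <- load_rules()
  expect_equal(length(rules), 22)
  expect_equal(vapply(rules, `[[`, integer(1), "id"), 1:22)
  expect_true(all(vapply(rules, function(e) length(e$predictions) >= 1, TRUE)))
})

test_that("each entry fires on its property and stays silent otherwise", {
  rules <- load_rules()
  # one firing signature per entry id
  sigs <- list(
    `1` = mk_sig(amax = "const"),
    `2` = mk_sig(amax = "inc", linear = c(TRUE, FALSE), origin = c(TRUE, FALSE)),
    `3` = mk_sig(amax = "inc", origin = c(TRUE, FALSE)),
    `4` = mk_sig(amax = "dec", zero_inf = c(TRUE, FALSE)),
    `5` = mk_sig(amax = "inc", amin = "inc", pos0 = c(TRUE, TRUE)),
    `6` = mk_sig(amax = "dec"),
    `7` = mk_sig(amax = "inc", amin = "dec"),
    `8` = mk_sig(amin = "inc", linear = c(FALSE, TRUE), origin = c(FALSE, TRUE)),
    `9` = mk_sig(amin = "inc", origin = c(FALSE, TRUE)),
    `10` = mk_sig(pos0 = c(FALSE, TRUE)),
    `11` = mk_sig(amin = "dec", zero_inf = c(FALSE, TRUE)),
    `12` = mk_sig(ord = "<"),
    `13` = mk_sig(ord = ">"),
    `14` = mk_sig(ord_inv = "<"),
    `15` = mk_sig(ord_inv = ">"),
    `16` = mk_sig(ord_inv = "="),
    `17` = mk_sig(ic50 = "const"),
    `18` = mk_sig(ic50 = "inc"),
    `19` = mk_sig(ic50 = "dec"),
    `20` = mk_sig(ratio = "const"),
    `21` = mk_sig(ratio = "inc"),
    `22` = mk_sig(ratio = "dec")
  )
  # a signature designed to fire nothing direction-dependent
  silent <- mk_sig(amax = "inc", amin = "inc", ic50 = "dec", ratio = "dec")
  for (id in c(2:16)) {
    fired <- classify(sigs[[as.character(id)]], rules)$fired$id
    expect_true(id %in% fired, label = paste("entry", id, "fires"))
  }
  # the constant-condition entries (1, 17, 20) fire on the all-const parts
  for (id in c(1, 17, 18, 19, 20, 21, 22)) {
    fired <- classify(sigs[[as.character(id)]], rules)$fired$id
    expect_true(id %in% fired, label = paste("entry", id, "fires"))
  }
  # non-firing check: entries 1-6, 8-9, 11-18, 20-21 silent on `silent`
  fired_silent <- classify(silent, rules)$fired$id
  for (id in c(1, 2, 3, 4, 6, 8, 9, 11, 12, 13, 14, 15, 16, 17, 18, 20, 21)) {
    expect_false(id %in% fired_silent, label = paste("entry", id, "silent"))
  }
})

test_that("classification reproduces the printed single-entry calls", {
  # Amax linear increasing through the origin -> F is A at the CLS
  s2 <- mk_sig(amax = "inc", linear = c(TRUE, FALSE), origin = c(TRUE, FALSE))
  surv <- classify(s2)$survivors
  expect_true(all(surv$f_mech == "A" & surv$f_pos == "at"))
  # IC50 constant -> F is A at the CLS
  surv17 <- classify(mk_sig(ic50 = "const"))$survivors
  expect_true(all(surv17$f_mech == "A" & surv17$f_pos == "at"))
  # Amax up + Amin down -> F is A after CLS, GR is A or C after F
  surv7 <- classify(mk_sig(amax = "inc", amin = "dec"))$survivors
  expect_true(all(surv7$f_mech == "A" & surv7$f_pos == "after"))
  expect_true(all(surv7$g_mech %in% c("A", "LC", "PC")))
  expect_true(all(surv7$order == "GR-after-F"))
})

test_that("contradictory signatures give an empty intersection, not an error", {
  bad <- mk_sig(amax = "const", amin = "inc", linear = c(FALSE, TRUE),
                origin = c(FALSE, TRUE))
  res <- classify(bad)
  expect_true(res$empty)
  expect_equal(nrow(res$survivors), 0)
})

test_that("the six canonical cases reproduce the printed verdicts", {
  pat <- tif2_pattern()
  verdicts <- c(`1` = FALSE, `2` = FALSE, `3` = FALSE, `4` = FALSE,
                `5` = TRUE, `6` = FALSE)
  for (case in names(verdicts)) {
    sc <- feasibility_scan(cfg_case(case), pat, n_samples = 2e4, seed = 42)
    expect_identical(sc$feasible, unname(verdicts[case]),
                     label = paste("case", case, "stochastic"))
    expect_identical(sc$analytic_verdict, unname(verdicts[case]),
                     label = paste("case", case, "analytic"))
  }
  # the feasible case comes with a parameter witness
  sc5 <- feasibility_scan(cfg_case(5), pat, n_samples = 2e4, seed = 42)
  expect_false(is.null(sc5$witness))
  env <- sc5$witness
  forms <- dr_param_forms(derive_TU(cfg_case(5)))
  num <- eval_param_forms(forms, lapply(env, `[`, 1))
  expect_identical(lf_shape(num$amax, const_tol = 1e-9)$direction, "inc")
  expect_identical(lf_shape(num$amin, const_tol = 1e-9)$direction, "dec")
})

test_that("case 6 admits Amax up / Amin down but never with IC50 down", {
  relaxed <- feasibility_scan(cfg_case(6), sign_pattern("inc", "dec"),
                              n_samples = 2e4, seed = 42)
  expect_true(relaxed$feasible)
  with_ic50 <- feasibility_scan(cfg_case(6),
                                sign_pattern("inc", "dec", ic50 = "dec",
                                             amax_gt_amin = FALSE),
                                n_samples = 1e5, seed = 42)
  expect_false(with_ic50$feasible)
})

test_that("analytic and stochastic verdicts agree whenever both defined", {
  pat <- tif2_pattern()
  for (cfg in enumerate_configurations()) {
    sc <- feasibility_scan(cfg, pat, n_samples = 1e4, seed = 9)
    if (!is.na(sc$analytic_verdict)) {
      expect_identical(sc$feasible, sc$analytic_verdict)
    }
  }
})

test_that("GR localisation intersects cofactor evidence", {
  cfgs <- enumerate_configurations()
  # the full repression pattern alone pins the unique configuration
  inf <- infer_gr_action(list(TIF2 = tif2_pattern()), configs = cfgs,
                         n_samples = 4000, seed = 2)
  expect_equal(names(inf$survivors), "F:A@after|GR:A@after|GR-after-F")
  expect_identical(inf$diagnosis, "consistent")

  # a trendless cofactor neither confirms nor contradicts
  phen <- sign_pattern("inc", "inc", "const", "const")
  inf2 <- infer_gr_action(list(TIF2 = tif2_pattern(), phen = phen),
                          configs = cfgs, n_samples = 4000, seed = 2)
  expect_equal(names(inf2$survivors), names(inf$survivors))

  # an impossible pattern empties the survivor set with a diagnosis
  impossible <- sign_pattern("const", "inc", ratio = "dec", amax_gt_amin = TRUE)
  inf3 <- infer_gr_action(list(bad = impossible),
                          configs = cfgs[1:4], n_samples = 2000, seed = 2)
  expect_identical(inf3$diagnosis, "model-inconsistent")
})
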