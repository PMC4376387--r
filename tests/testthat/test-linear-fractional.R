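test_that("evaluation and canonical form behave", {
  f <- linear_fractional(1, 2, 2, 2)  # canonicalised to c = 1
  expect_equal(f$c, 1)
  expect_equal(lf_eval(f, 0), 0.5)
  expect_equal(lf_eval(f, Inf), 1)
  expect_error(linear_fractional(1, 1, 0, 0), "degenerate")
})

test_that("composition closure holds over random coefficients", {
  set.seed(42)
  for (i in 1:50) {
    f <- linear_fractional(rnorm(1), rnorm(1), rnorm(1), runif(1, 0.5, 2),
                           canonical = FALSE)
    g <- linear_fractional(runif(1, 0.1, 2), runif(1, 0.1, 2),
                           1, runif(1, 0.1, 2), canonical = FALSE)
    h <- lf_compose(f, g)
    x <- c(0.1, 0.7, 1.3, 5, 20)
    expect_equal(lf_eval(h, x), lf_eval(f, lf_eval(g, x)), tolerance = 1e-12)
  }
})

test_that("shape classification follows the ad vs bc rule", {
  s <- lf_shape(linear_fractional(1, 2, 1, 1))   # ad = 1 < bc = 2
  expect_identical(s$direction, "inc")
  expect_equal(s$half_max, 1)
  expect_equal(s$reciprocal_half_max, 0.5)

  expect_identical(lf_shape(linear_fractional(2, 2, 1, 1))$direction, "const")
  expect_identical(lf_shape(linear_fractional(2, 1, 1, 1))$direction, "dec")

  lin <- lf_shape(linear_fractional(0, 3, 1, 0))
  expect_true(lin$linear_through_origin)
  sat <- lf_shape(linear_fractional(0, 1, 1, 1))  # x/(1+x)
  expect_false(sat$linear_through_origin)
})

test_that("classified direction matches finite differences", {
  set.seed(7)
  for (i in 1:40) {
    lf <- linear_fractional(runif(1, 0, 3), runif(1, 0, 3), 1, runif(1, 0, 2),
                            canonical = FALSE)
    s <- lf_shape(lf, const_tol = 0)
    v <- lf_eval(lf, c(0.5, 1, 5, 20, 80))
    d <- diff(v)
    if (s$direction == "inc") expect_true(all(d >= -1e-12))
    if (s$direction == "dec") expect_true(all(d <= 1e-12))
  }
})
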