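test_that("box_cox matches its defining algebra and the log limit", {
  expect_equal(box_cox(c(1, 1, 1), 0.7), c(0, 0, 0))
  expect_equal(box_cox(c(2, 5), 1), c(1, 4))
  expect_equal(box_cox(exp(2), 0), 2)
  expect_equal(box_cox(4, 0.5), 2)
  # continuity at lambda = 0
  y <- seq(0.1, 100, length.out = 200)
  expect_lt(max(abs(box_cox(y, 1e-9) - log(y))), 1e-6)
  # strict monotonicity in y for all lambda
  y <- sort(exp(runif(100, -4, 6)))
  for (l in c(-2, -1, -0.3, 0, 0.5, 1, 2)) {
    expect_true(all(diff(box_cox(y, l)) > 0), label = sprintf("lambda=%g", l))
  }
})

test_that("inv_box_cox inverts box_cox across the parameter grid", {
  y <- c(0.01, 0.5, 3, 10, 1000)
  for (l in c(-2, -1, 0, 0.5, 1, 2)) {
    expect_equal(inv_box_cox(box_cox(y, l), l), y, tolerance = 1e-8)
  }
  expect_equal(inv_box_cox(2, 0.5), 4)
  for (l in c(-1, 0, 0.7)) expect_equal(inv_box_cox(0, l), 1)
  expect_error(inv_box_cox(c(0, -3), 1), "no real inverse")
})

test_that("box_cox positivity policies reject or shift non-positive input", {
  expect_error(box_cox(c(1, -2, 0, 5), 0.5), "2 value")
  out <- suppressMessages(box_cox(c(1, -2, 0, 5), 0.5, positivity = "shift"))
  expect_true(is.numeric(out) && all(is.finite(out)))
  expect_equal(attr(out, "shift"), 1e-6 * 7 + 2)
})

test_that("rint maps ranks to normal scores and ignores scale/location", {
  expect_equal(rint(c(3, 1, 2))[3], 0)
  y <- sort(rnorm(50))
  expect_true(all(diff(rint(y)) > 0))
  y2 <- rnorm(200)
  expect_equal(rint(y2), rint(2 * y2 + 7))
  # Blom offset at n = 5, and average ranks under ties
  expect_equal(rint(1:5), qnorm(((1:5) - 3 / 8) / 5.25))
  expect_equal(rint(c(1, 2, 2, 3))[2], rint(c(1, 2, 2, 3))[3])
  expect_error(rint(rep(1, 10)), "constant")
  expect_error(rint(3), "at least 2")
})

test_that("anderson_darling agrees with the order-statistic formula", {
  set.seed(7)
  for (x in list(rnorm(200), rexp(150), rt(120, 4))) {
    expect_equal(anderson_darling(x), ad_stat_oracle(x), tolerance = 1e-8)
  }
})

test_that("anderson_darling separates normal from exponential samples", {
  set.seed(11)
  a_norm <- anderson_darling(rnorm(10000))
  a_exp <- anderson_darling(rexp(10000))
  expect_lt(a_norm, 0.752)          # below the conventional 5% point
  expect_gt(a_exp, 10 * a_norm)
  x <- rt(500, 5)
  expect_equal(anderson_darling(x), anderson_darling(3 * x - 7), tolerance = 1e-10)
  expect_error(anderson_darling(rep(2, 50)), "zero-variance")
  expect_error(anderson_darling(rnorm(5)), "at least 8")
})

test_that("rint output is accepted as normal by the A^2 diagnostic", {
  set.seed(13)
  y <- rexp(5000)   # continuous, no ties
  expect_gt(nortest::ad.test(rint(y))$p.value, 0.05)
})

test_that("transform_phenotype appends the requested scale column", {
  d <- tibble::tibble(id = 1:5, y = c(1, 4, 9, 16, 25))
  out <- transform_phenotype(d, "y", scale = "boxcox", lambda = 0.5)
  expect_equal(out$y_boxcox, (sqrt(d$y) - 1) / 0.5)
  out2 <- transform_phenotype(d, "y", scale = "rint", new_col = "z")
  expect_named(out2, c("id", "y", "z"))
  expect_error(transform_phenotype(d, "nope", scale = "log"), "not found")
})
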