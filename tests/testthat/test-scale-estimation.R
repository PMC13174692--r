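test_that("relative residuals r* sum to zero and the objective is scale-free", {
  fx <- sim_fixture(n = 1000, lambda0 = 0.5, seed = 12, alpha = 1)
  d <- fx$d
  for (lam in c(0, 0.5, 1.5)) {
    obj <- wald_objective(d, "y", c("G", "C1"), focal = "C1", lambda = lam,
                          B = 40, seed = 3)
    r <- attr(obj, "r_star")
    expect_equal(sum(r), 0, tolerance = 1e-10)
    expect_gte(as.numeric(obj), 0)
  }
  # multiplying the focal covariate by a positive constant: alpha and its
  # mean scale together, the objective is unchanged
  o1 <- wald_objective(d, "y", c("G", "C1"), focal = "C1", lambda = 0.5,
                       B = 40, seed = 3)
  d2 <- dplyr::mutate(d, C1 = 2.5 * C1)
  o2 <- wald_objective(d2, "y", c("G", "C1"), focal = "C1", lambda = 0.5,
                       B = 40, seed = 3)
  expect_equal(as.numeric(o1), as.numeric(o2), tolerance = 1e-6)
})

test_that("the objective dips at the generating scale", {
  set.seed(61)
  sc <- sim_scenario(n = 1500, lambda0 = 0.5, alpha = 1.5)
  vals <- replicate(15, {
    d <- siqreg:::simulate_core(sc)
    W <- siqreg:::multiplier_weights(1500, 40)
    X <- siqreg:::sim_design(d)
    vapply(c(-0.5, 0.5, 1.5), function(l)
      siqreg:::siqreg_eval(l, d$y, X, 3L, estimation_taus(), W)$obj, numeric(1))
  })
  m <- rowMeans(vals)
  expect_lt(m[2], m[1])
  expect_lt(m[2], m[3])
})

test_that("degenerate compressive scales are flagged, not selected", {
  fx <- sim_fixture(n = 1500, lambda0 = 0.5, seed = 77,
                    error = "student_t", df = 3)
  W <- siqreg:::multiplier_weights(1500, 30, 5)
  ev <- siqreg:::siqreg_eval(-5, fx$d$y, fx$X, 3L, estimation_taus(), W)
  expect_true(ev$uninformative[1])
  expect_true(is.na(ev$obj[1]))
})

test_that("single-covariate estimation recovers the scale and reports a trace", {
  fx <- sim_fixture(n = 2000, lambda0 = 0.5, seed = 21, alpha = 1)
  est <- estimate_lambda_one(fx$d, "y", c("G", "C1"), focal = "C1",
                             B = 32, seed = 7, tol = 0.01)
  expect_lt(abs(est$lambda_hat - 0.5), 0.6)   # single replicate, B = 32
  expect_false(est$uninformative)
  expect_false(est$boundary)
  expect_s3_class(est$trace, "tbl_df")
  expect_true(all(diff(est$trace$lambda) > 0))
  # seed determinism of the whole search
  est2 <- estimate_lambda_one(fx$d, "y", c("G", "C1"), focal = "C1",
                              B = 32, seed = 7, tol = 0.01)
  expect_identical(est$lambda_hat, est2$lambda_hat)
})

test_that("meta-analysis pools by inverse variance", {
  one <- meta_analyze(tibble::tibble(lambda_hat = 0.4, se = 0.1))
  expect_equal(one$lambda0, 0.4)
  expect_equal(one$se, 0.1)
  eq <- meta_analyze(tibble::tibble(lambda_hat = c(0, 1), se = c(0.3, 0.3)))
  expect_equal(eq$lambda0, 0.5)
  iv <- meta_analyze(tibble::tibble(lambda_hat = c(0, 1), se = c(1, 0.5)))
  expect_equal(iv$lambda0, 0.8)
  expect_equal(iv$se, sqrt(1 / (1 + 4)))
  expect_gt(meta_analyze(tibble::tibble(lambda_hat = c(0, 1, 0.5),
                                        se = c(0.05, 0.05, 0.05)))$q, 0)
  expect_error(meta_analyze(tibble::tibble(lambda_hat = NA_real_, se = 0.1)),
               "no informative")
})

test_that("subsampling assignments are disjoint, seeded, and yield a CI", {
  fx <- sim_fixture(n = 1600, lambda0 = 0.5, seed = 31, alpha = 1.5)
  ss <- subsample_ci(fx$d, "y", "C1", R = 4, seed = 11, B = 16,
                     center = 0.5, tol = 0.05)
  expect_equal(sort(unique(ss$subsamples$subsample)), 1:4)
  expect_gte(ss$se, 0)
  expect_lt(ss$ci_low, 0.5)
  expect_gt(ss$ci_high, 0.5)
  ss2 <- subsample_ci(fx$d, "y", "C1", R = 4, seed = 11, B = 16,
                      center = 0.5, tol = 0.05)
  expect_equal(ss$subsamples$lambda_hat, ss2$subsamples$lambda_hat)
  expect_error(subsample_ci(fx$d, "y", "C1", R = 1), "R >= 2")
})

test_that("end-to-end scale estimation pools covariates and flags noise ones", {
  set.seed(67)
  sc <- sim_scenario(n = 2400, lambda0 = 0.5, beta_g = 0.3, alpha = c(1.2, 0.8))
  d <- simulate(sc, seed = 41)
  d$noise <- rnorm(nrow(d))   # genuinely uninformative covariate
  est <- estimate_scale(d, "y", c("C1", "C2", "noise"), B = 16, R = 3,
                        seed = 13, tol = 0.02)
  expect_s3_class(est, "scale_estimate")
  td <- tidy(est)
  expect_equal(td$covariate, c("C1", "C2", "noise"))
  expect_true(td$uninformative[td$covariate == "noise"])
  expect_false(any(td$uninformative[td$covariate != "noise"]))
  expect_lt(abs(est$lambda_hat - 0.5), 0.4)
  expect_true(est$ci_low < est$lambda_hat && est$lambda_hat < est$ci_high)
  g <- glance(est)
  expect_equal(g$n, 2400)
  expect_true(is.finite(g$ad_default) && is.finite(g$ad_siqreg))
  # z-test of the default scale is reported against lambda0 = 1
  expect_equal(est$test_default_scale$z, (est$lambda_hat - 1) / est$se,
               tolerance = 1e-12)
})

test_that("estimates are stable under permuting individuals", {
  fx <- sim_fixture(n = 2000, lambda0 = 0, seed = 51, alpha = 1.5)
  est <- estimate_lambda_one(fx$d, "y", c("G", "C1"), focal = "C1",
                             B = 32, seed = 9, tol = 0.02)
  perm <- fx$d[sample(nrow(fx$d)), ]
  est_p <- estimate_lambda_one(perm, "y", c("G", "C1"), focal = "C1",
                               B = 32, seed = 9, tol = 0.02)
  expect_lt(abs(est$lambda_hat - est_p$lambda_hat), 0.2)
})
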