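test_that("scenario validation enforces the stated parameter ranges", {
  expect_error(sim_scenario(50, 1), "n >= 100")
  expect_error(sim_scenario(500, 1, maf = 0), "maf")
  expect_error(sim_scenario(500, 1, error = "student_t", df = 2), "df > 2")
  expect_error(sim_scenario(500, 1, gamma = -0.1), "gamma")
  sc <- sim_scenario(500, 0.5, gamma = 0.1)
  expect_s3_class(sc, "sim_scenario")
})

test_that("identity scale gives y = 1 + y* and draws are seed-deterministic", {
  sc <- sim_scenario(n = 500, lambda0 = 1)
  d <- simulate(sc, seed = 1)
  expect_equal(d$y, 1 + d$y_latent, tolerance = 1e-12)
  d2 <- simulate(sc, seed = 1)
  expect_identical(d, d2)
  d3 <- simulate(sc, seed = 2)
  expect_false(identical(d$y, d3$y))
  expect_true(all(d$y > 0))
  # log scale: y = exp(y*)
  dl <- simulate(sim_scenario(n = 300, lambda0 = 0), seed = 4)
  expect_equal(dl$y, exp(dl$y_latent), tolerance = 1e-12)
})

test_that("genotype frequencies and error structure match the model", {
  sc <- sim_scenario(n = 10000, lambda0 = 0.5, maf = 0.3)
  d <- simulate(sc, seed = 9)
  se_g <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(d$G) - 0.6), 3 * se_g)
  # homoscedastic: |residual| shows no genotype trend; gamma > 0: it does
  slope_z <- function(dd) {
    r <- abs(resid(lm(y_latent ~ G + C1, data = dd)))
    f <- summary(lm(r ~ dd$G))
    f$coefficients[2, 3]
  }
  expect_lt(abs(slope_z(d)), 3)
  dg <- simulate(sim_scenario(n = 10000, lambda0 = 0.5, gamma = 0.3), seed = 9)
  expect_gt(slope_z(dg), 5)
})

test_that("infeasible scenarios are resampled or rejected", {
  # boundary well inside the latent distribution: > 10% infeasible, rejected
  sc_bad <- sim_scenario(n = 1000, lambda0 = 1, beta0 = -1)
  expect_error(simulate(sc_bad, seed = 1), "infeasible|Scenario")
  # boundary brushing the tail: resampled, all draws valid
  sc_edge <- sim_scenario(n = 5000, lambda0 = 0.5, error = "student_t", df = 3)
  d <- simulate(sc_edge, seed = 2)
  expect_true(all(1 + 0.5 * d$y_latent > 0))
  expect_gte(attr(d, "n_resampled"), 0)
})

test_that("harnesses return tidy summaries with their replicate detail", {
  r <- run_recovery(lambda0s = 0.5, n = 400, n_reps = 2, B = 12,
                    seed = 5, tol = 0.05)
  expect_s3_class(r, "tbl_df")
  expect_true(all(c("lambda0", "estimator", "mean_lambda_hat", "bias", "mc_se")
                  %in% names(r)))
  expect_setequal(unique(attr(r, "reps")$estimator), c("siqreg", "warped"))
  rp <- run_profile_shapes(lambda0 = 0, n = 1500, scales = c("latent", "default"),
                           B = 40, B_est = 16, seed = 6, tol = 0.05)
  expect_named(rp, c("scale", "slope", "se", "z", "lambda_hat"))
  expect_equal(nrow(rp), 2)
})

test_that("profile trend propagates the effect covariance correctly", {
  taus <- seq(0.1, 0.9, by = 0.2)
  # exact linear profile: slope recovered, z = slope / se with known cov
  betas <- 1 + 2 * taus
  tr <- profile_trend(betas, taus, diag(5) * 0.25)
  expect_equal(tr$slope, 2, tolerance = 1e-10)
  ct <- taus - mean(taus)
  w <- ct / sum(ct^2)
  expect_equal(tr$se, 0.5 * sqrt(sum(w^2)), tolerance = 1e-10)
})
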