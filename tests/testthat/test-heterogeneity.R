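test_that("contrast matrix has the successive-difference pattern and full rank", {
  expect_equal(contrast_matrix(2), matrix(c(1, -1), 1))
  expect_equal(contrast_matrix(3),
               rbind(c(1, -1, 0), c(0, 1, -1)))
  expect_equal(qr(contrast_matrix(9))$rank, 8)
  expect_error(contrast_matrix(1), "K >= 2")
})

test_that("Wald statistic matches hand calculation and degenerates correctly", {
  # equal effects: no heterogeneity regardless of covariance
  r0 <- wald_het_test(rep(0.3, 5), diag(5) * 0.2)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # K=2, betas (0,1), identity cov: A b = -1, A S A' = 2, T = 0.5
  r1 <- wald_het_test(c(0, 1), diag(2))
  expect_equal(r1$statistic, 0.5)
  expect_equal(r1$df, 1L)
  expect_equal(r1$p_value, pchisq(0.5, 1, lower.tail = FALSE))
  # affine rescaling of the phenotype leaves T unchanged
  b <- c(0.1, 0.4, 0.2)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_equal(wald_het_test(7 * b, 49 * S)$statistic,
               wald_het_test(b, S)$statistic, tolerance = 1e-10)
  # singular contrast covariance: pseudo-inverse with reduced effective df
  S_sing <- diag(c(1, 1, 0, 0))
  expect_warning(r2 <- wald_het_test(c(0, 1, 0, 1), S_sing),
                 "pseudo-inverse")
  expect_lt(r2$df, 3)
})

test_that("null distribution of T is chi-squared(K-1) with known covariance", {
  set.seed(31)
  K <- 5
  L <- chol(0.5 * diag(K) + 0.5)
  stats <- replicate(2000, {
    beta <- drop(rnorm(K) %*% L)
    wald_het_test(beta, crossprod(L))$statistic
  })
  ks <- stats::ks.test(stats, pchisq, df = K - 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("F calibration corrects the finite-bootstrap covariance", {
  set.seed(37)
  K <- 7
  B <- 50
  p_chi <- p_f <- numeric(800)
  for (i in seq_len(800)) {
    beta <- rnorm(K)                      # truth: no heterogeneity, unit cov
    draws <- matrix(rnorm(B * K), B, K)
    S <- cov(draws)
    p_chi[i] <- wald_het_test(beta, S)$p_value
    p_f[i] <- wald_het_test(beta, S, cov_df = B - 1L)$p_value
  }
  rate_chi <- mean(p_chi < 0.05)
  rate_f <- mean(p_f < 0.05)
  expect_gt(rate_chi, 0.08)   # chi-squared reference is anticonservative here
  band <- qbinom(c(0.025, 0.975), 800, 0.05) / 800
  expect_gte(rate_f, band[1])
  expect_lte(rate_f, band[2])
})

test_that("quantile_het_scan guards extreme levels and validates inputs", {
  fx <- sim_fixture(n = 600, lambda0 = 1, seed = 3)
  expect_warning(
    res <- quantile_het_scan(fx$d, "y_latent", "G", covariates = "C1",
                             scale = "latent", B = 50, seed = 1),
    "extreme quantile"
  )
  expect_s3_class(res, "het_result")
  expect_true(all(res$taus %in% testing_taus()))
  expect_true(all(600 * pmin(res$taus, 1 - res$taus) >= 30))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_equal(length(res$se), length(res$betas))
  d0 <- fx$d
  d0$G <- 1
  expect_error(quantile_het_scan(d0, "y", "G", scale = "default"),
               "zero variance")
  g <- glance(res)
  expect_named(g, c("statistic", "df", "p_value", "scale", "k_taus"))
})

test_that("the scan is calibrated on the true latent scale", {
  set.seed(41)
  sc <- sim_scenario(n = 1500, lambda0 = 0.5, beta_g = 0.4, alpha = 1)
  p <- replicate(80, {
    d <- siqreg:::simulate_core(sc)
    X <- siqreg:::sim_design(d)
    siqreg:::het_pvalue_core(d$y_latent, X, 2L, B = 80)
  })
  band <- qbinom(c(0.025, 0.975), 80, 0.05) / 80
  rate <- mean(p < 0.05)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})
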