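test_that("check loss weights residuals asymmetrically", {
  expect_equal(check_loss(-2, 0.5), 1)
  expect_equal(check_loss(1, 0.9), 0.9)
  expect_equal(check_loss(-1, 0.9), 0.1)
  u <- seq(-3, 3, by = 0.5)
  expect_true(all(check_loss(u, 0.3) >= 0))
  expect_identical(which(check_loss(u, 0.3) == 0), which(u == 0))
})

test_that("smoothed loss matches quadrature of the convolution and its stated derivative", {
  # closed form vs adaptive quadrature of the defining integral
  for (u in c(-2, -0.3, 0, 0.7, 2)) {
    for (tau in c(0.25, 0.5, 0.9)) {
      expect_equal(smoothed_loss(u, tau, 1), smoothed_loss_quad(u, tau, 1),
                   tolerance = 1e-7)
      expect_equal(smoothed_loss(u, tau, 0.2), smoothed_loss_quad(u, tau, 0.2),
                   tolerance = 1e-7)
    }
  }
  # h -> 0 recovers the raw check loss
  u <- seq(-3, 3, by = 1)
  expect_equal(smoothed_loss(u, 0.3, 1e-6), check_loss(u, 0.3), tolerance = 1e-5)
  # derivative tau - Phi(-u/h): central difference at u = 0, tau = 0.7
  h <- 0.5
  num <- (smoothed_loss(1e-5, 0.7, h) - smoothed_loss(-1e-5, 0.7, h)) / 2e-5
  expect_equal(num, 0.2, tolerance = 1e-6)
  quad <- (smoothed_loss_quad(1e-4, 0.7, h) - smoothed_loss_quad(-1e-4, 0.7, h)) / 2e-4
  expect_equal(quad, 0.2, tolerance = 1e-5)
  expect_error(smoothed_loss(1, 0.5, -1), "positive")
})

test_that("bandwidth rule follows the stated rate and monotonicities", {
  expect_equal(bandwidth_rule(1000, 2), ((2 + log(1000)) / 1000)^0.4)
  ns <- c(500, 2000, 8000, 32000)
  expect_true(all(diff(vapply(ns, bandwidth_rule, numeric(1), p = 2)) < 0))
  expect_true(all(diff(vapply(1:6, function(p) bandwidth_rule(1000, p), numeric(1))) > 0))
  expect_error(bandwidth_rule(3, 5), "n > p")
})

test_that("fit_quantile approaches the exact check-loss minimizer", {
  # heavy-outlier intercept-only case: a tight bandwidth keeps the smoothed
  # median next to the exact one despite the outlier (n is tiny, so the
  # default dispersion-scaled bandwidth would oversmooth)
  d <- tibble::tibble(y = c(1, 2, 3, 4, 100))
  fit <- fit_quantile(d, "y", character(0), taus = 0.5, bandwidth = 0.01)
  exact <- exact_qr_oracle(d$y, matrix(1, 5, 1), 0.5)
  expect_lt(abs(fit$coefficients[1, 1] - exact), 0.05 * sd(d$y))
  # noiseless line: slope -> 2 as h -> 0
  set.seed(5)
  d2 <- tibble::tibble(x = rnorm(200))
  d2$y <- 2 * d2$x
  f_small <- fit_quantile(d2, "y", "x", taus = 0.5, bandwidth = 1e-4)
  expect_equal(unname(f_small$coefficients["x", 1]), 2, tolerance = 1e-3)
})

test_that("smoothed fits track the exact oracle over random instances and h -> 0", {
  set.seed(17)
  diffs_h <- c()
  for (i in 1:10) {
    p <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
    n <- if (p == 3) sample(250:300, 1) else sample(300:450, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n) * runif(1, 0.5, 2)
    tau <- runif(1, 0.3, 0.7)
    core <- siqreg:::smqr_core(y, X, tau)
    exact <- exact_qr_oracle(y, X, tau)
    expect_lt(max(abs(core$coef[, 1] - exact)), 0.05 * sd(y))
    if (i <= 4) {
      h0 <- bandwidth_rule(n, p)
      d_big <- max(abs(siqreg:::smqr_core(y, X, tau, h = h0)$coef[, 1] - exact))
      d_small <- max(abs(siqreg:::smqr_core(y, X, tau, h = h0 / 8)$coef[, 1] - exact))
      diffs_h <- rbind(diffs_h, c(d_big, d_small))
    }
  }
  expect_lt(mean(diffs_h[, 2]), mean(diffs_h[, 1]))
})

test_that("coefficients are equivariant to scaling and shifting the response", {
  set.seed(19)
  d <- tibble::tibble(x = rnorm(300))
  d$y <- 1 + 0.5 * d$x + rnorm(300)
  taus <- c(0.25, 0.5, 0.75)
  base <- fit_quantile(d, "y", "x", taus = taus)$coefficients
  d$y3 <- 3 * d$y
  scaled <- fit_quantile(d, "y3", "x", taus = taus)$coefficients
  expect_equal(scaled, 3 * base, tolerance = 1e-4)
  d$ys <- d$y + 10
  shifted <- fit_quantile(d, "ys", "x", taus = taus)$coefficients
  expect_equal(shifted["x", ], base["x", ], tolerance = 1e-4)
  expect_equal(shifted["(Intercept)", ], base["(Intercept)", ] + 10, tolerance = 1e-4)
})

test_that("homoscedastic Gaussian slopes are constant across quantile levels", {
  set.seed(23)
  n <- 5000
  d <- tibble::tibble(x = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n)
  fit <- fit_quantile(d, "y", "x", taus = c(0.25, 0.5, 0.75))
  S <- bootstrap_cov(fit, "x", B = 100, seed = 1)
  se <- sqrt(diag(S))
  expect_true(all(abs(fit$coefficients["x", ] - 0.5) < 3 * se))
  # fitted values at the covariate mean are ordered in tau
  at_mean <- fit$coefficients["(Intercept)", ]
  expect_true(all(diff(at_mean) > 0))
})

test_that("bootstrap covariance is PSD, seeded, and shrinks with n", {
  set.seed(29)
  d <- tibble::tibble(x = rnorm(1000))
  d$y <- 1 + 0.5 * d$x + rnorm(1000)
  fit <- fit_quantile(d, "y", "x", taus = c(0.25, 0.5, 0.75))
  S1 <- bootstrap_cov(fit, "x", B = 120, seed = 99)
  S2 <- bootstrap_cov(fit, "x", B = 120, seed = 99)
  expect_equal(unclass(S1), unclass(S2))
  expect_true(all(diag(S1) > 0))
  expect_true(all(eigen(S1, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_error(bootstrap_cov(fit, "x", B = 1), "B >= 2")
  expect_error(bootstrap_cov(fit, "nope", B = 50), "does not name")
  # sampling variance roughly proportional to 1/n
  d4 <- tibble::tibble(x = rnorm(4000))
  d4$y <- 1 + 0.5 * d4$x + rnorm(4000)
  fit4 <- fit_quantile(d4, "y", "x", taus = c(0.25, 0.5, 0.75))
  S4 <- bootstrap_cov(fit4, "x", B = 120, seed = 99)
  ratio <- mean(diag(S1)) / mean(diag(S4))
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("degenerate designs and inputs are rejected", {
  d <- tibble::tibble(x = rnorm(50))
  d$x2 <- 2 * d$x
  d$y <- rnorm(50)
  expect_error(fit_quantile(d, "y", c("x", "x2")), "rank deficient")
  d$y[1] <- NA
  expect_error(fit_quantile(d, "y", "x"), "missing values")
  expect_error(fit_quantile(d, "y", "zz"), "Missing column")
  expect_error(siqreg:::smqr_core(rnorm(50), matrix(1, 50, 1), c(0.5, 0.25)),
               "strictly increasing")
})
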