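# Synthetic-data generator: latent additive model
#   y* = beta0 + betaG * G + alpha . C + eps
# observed on the default scale through the inverse Box-Cox map
#   y = (1 + lambda0 y*)^(1/lambda0)   (exp(y*) at lambda0 = 0),
# with Gaussian, Student-t, or genotype-heteroscedastic errors
#   eps_i = exp(gamma * G_i) * z_i.

#' Define a latent-additive simulation scenario
#'
#' @param n Sample size (>= 100).
#' @param lambda0 True Box-Cox exponent linking latent and default scales.
#' @param beta_g Additive genetic effect on the latent scale.
#' @param alpha Covariate effect(s) on the latent scale (vector gives several
#'   independent standard-normal covariates).
#' @param beta0 Latent intercept. Default (`NULL`) places the inverse-Box-Cox
#'   feasibility boundary four latent standard deviations away:
#'   `-1/lambda0 + sign(lambda0) * 4 * sd(y*)` for `lambda0 != 0`, else 0.
#'   This keeps the observation map visibly nonlinear over the latent range
#'   (the regime that identifies the scale) while the error-resampling policy
#'   absorbs the rare boundary violations.
#' @param maf Allele frequency of the biallelic genotype `G ~ Binomial(2, maf)`.
#' @param error Latent error family: `"gaussian"` or `"student_t"`.
#' @param df Degrees of freedom for Student-t errors (> 2).
#' @param gamma Heteroscedasticity strength: errors are multiplied by
#'   `exp(gamma * G)`, inducing genuine quantile-dependent genetic effects on
#'   the latent scale when `gamma > 0`.
#' @return A validated `sim_scenario` object for [simulate()].
#' @examples
#' sc <- sim_scenario(n = 500, lambda0 = 0.5)
#' d <- simulate(sc, seed = 1)
#' @export
sim_scenario <- function(n, lambda0, beta_g = 0.3, alpha = 0.5, beta0 = NULL,
                         maf = 0.3, error = c("gaussian", "student_t"),
                         df = 3, gamma = 0) {
  error <- match.arg(error)
  stopifnot(n >= 100, is.finite(lambda0), maf > 0, maf <= 0.5, gamma >= 0)
  if (error == "student_t" && df <= 2)
    abort("Student-t errors need df > 2 (finite variance).")
  err_var <- if (error == "student_t") df / (df - 2) else 1
  sd_latent <- sqrt(beta_g^2 * 2 * maf * (1 - maf) + sum(alpha^2) +
                      err_var * exp(2 * gamma * 2))
  if (is.null(beta0)) {
    beta0 <- if (abs(lambda0) < 1e-8) 0 else -1 / lambda0 + sign(lambda0) * 4 * sd_latent
  }
  structure(
    list(n = as.integer(n), lambda0 = lambda0, beta_g = beta_g, alpha = alpha,
         beta0 = beta0, maf = maf, error = error, df = df, gamma = gamma,
         sd_latent = sd_latent),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Latent-additive scenario: n = %d, lambda0 = %.3g, beta_g = %.3g, alpha = (%s)\n",
    x$n, x$lambda0, x$beta_g, paste(signif(x$alpha, 3), collapse = ", ")))
  cat(sprintf("  beta0 = %.3g, maf = %.2f, errors %s%s, gamma = %.3g\n",
              x$beta0, x$maf, x$error,
              if (x$error == "student_t") sprintf("(df=%g)", x$df) else "",
              x$gamma))
  invisible(x)
}

# draws one dataset from the current RNG state; resamples the error term of
# individuals whose latent value falls outside the inverse-Box-Cox domain
simulate_core <- function(sc) {
  n <- sc$n
  m <- length(sc$alpha)
  G <- rbinom(n, 2, sc$maf)
  C <- matrix(rnorm(n * m), n, m)
  draw_z <- function(k) switch(sc$error,
                               gaussian = rnorm(k),
                               student_t = rt(k, df = sc$df))
  z <- draw_z(n)
  eps <- if (sc$gamma > 0) exp(sc$gamma * G) * z else z
  ystar <- sc$beta0 + sc$beta_g * G + drop(C %*% sc$alpha) + eps
  n_resampled <- 0L
  if (abs(sc$lambda0) >= 1e-8) {
    fixed_part <- ystar - eps
    bad <- which(1 + sc$lambda0 * ystar <= 0)
    if (length(bad) > 0.1 * n)
      abort(sprintf(
        "Scenario infeasible: %d/%d draws outside the inverse-Box-Cox domain; shift beta0 away from the boundary.",
        length(bad), n))
    n_resampled <- length(bad)
    tries <- 0L
    while (length(bad) > 0) {
      tries <- tries + 1L
      if (tries > 100L)
        abort("Scenario rejected: latent draws still infeasible after 100 resampling rounds; shift beta0.")
      z_new <- draw_z(length(bad))
      eps[bad] <- if (sc$gamma > 0) exp(sc$gamma * G[bad]) * z_new else z_new
      ystar[bad] <- fixed_part[bad] + eps[bad]
      bad <- bad[1 + sc$lambda0 * ystar[bad] <= 0]
    }
  }
  y <- inv_box_cox(ystar, sc$lambda0)
  out <- tibble(id = seq_len(n), G = G)
  colnames(C) <- paste0("C", seq_len(m))
  out <- dplyr::bind_cols(out, as_tibble(C))
  out$y_latent <- ystar
  out$y <- y
  attr(out, "n_resampled") <- n_resampled
  attr(out, "scenario") <- sc
  out
}

#' Simulate a dataset from a scenario
#'
#' Draws genotype, covariates, latent phenotype, and the default-scale
#' phenotype (via the inverse Box-Cox map). Individuals whose latent value
#' falls outside the inverse-transform domain have their error term redrawn
#' (up to 100 rounds); the count is recorded in attribute `"n_resampled"`,
#' and a scenario whose first draw is more than 10% infeasible is rejected.
#' Identical scenario and seed give an identical dataset.
#'
#' @param object A [sim_scenario()].
#' @param nsim Number of datasets (a list is returned when `nsim > 1`).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A tibble with columns `id`, `G`, `C1...`, `y_latent`, `y` (or a
#'   list of such tibbles).
#' @exportS3Method stats::simulate
simulate.sim_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (nsim == 1) return(simulate_core(object))
  lapply(seq_len(nsim), function(i) simulate_core(object))
}

# design matrix [1, G, C...] from a simulated dataset
sim_design <- function(d) {
  ccols <- grep("^C[0-9]+$", names(d), value = TRUE)
  X <- cbind(`(Intercept)` = 1, G = d$G, as.matrix(d[ccols]))
  X
}

# exact central binomial acceptance band for a rejection rate, as rates
binom_band <- function(n_reps, alpha = 0.05, level = 0.95) {
  c(lower = qbinom((1 - level) / 2, n_reps, alpha) / n_reps,
    upper = qbinom(1 - (1 - level) / 2, n_reps, alpha) / n_reps)
}

# ---- harnesses --------------------------------------------------------------

# per-replicate scale estimate: one estimate per covariate (all covariates in
# the design), equal-weight meta-analysis of the informative ones; NA when
# every covariate is uninformative
siqreg_lambda_rep <- function(y, X, taus, B, interval, grid_step, refine_step,
                              tol) {
  est <- estimate_lambda_core(y, X, focals = seq(3L, ncol(X)), taus = taus,
                              B = B, interval = interval, grid_step = grid_step,
                              refine_step = refine_step, tol = tol)
  lams <- vapply(est, `[[`, numeric(1), "lambda_hat")
  uninf <- vapply(est, `[[`, logical(1), "uninformative")
  ok <- !uninf & is.finite(lams)
  if (any(ok)) mean(lams[ok]) else NA_real_
}


#' Scale-recovery study
#'
#' Simulates latent-additive data over a grid of true `lambda0`, estimates
#' the scale with the SIQReg (quantile-heterogeneity) estimator and the
#' Gaussian-likelihood comparator on identical replicates, and summarizes
#' bias and Monte-Carlo error per estimator.
#'
#' @param lambda0s True scale exponents to sweep.
#' @param n Sample size per replicate.
#' @param n_reps Replicates per `lambda0`.
#' @param error,df Latent error family (see [sim_scenario()]).
#' @param estimators Subset of `c("siqreg", "warped")`.
#' @param B Bootstrap replicates per SIQReg objective evaluation.
#' @param taus Estimation quantile levels.
#' @param seed Integer seed; replicates are seeded reproducibly from it.
#' @param beta_g,alpha,maf Scenario parameters (see [sim_scenario()]).
#' @param interval,grid_step,refine_step,tol Search controls.
#' @return Tibble with one row per `(lambda0, estimator)`: `mean_lambda_hat`,
#'   `bias`, `mc_se`, `n_reps`; per-replicate estimates in attribute
#'   `"reps"`.
#' @export
run_recovery <- function(lambda0s = c(-0.5, 0, 0.5, 1), n = 10000L,
                         n_reps = 1000L, error = "gaussian", df = 3,
                         estimators = c("siqreg", "warped"), B = 100L,
                         taus = estimation_taus(), seed = 1L,
                         beta_g = 0.3, alpha = 0.5, maf = 0.3,
                         interval = c(-5, 5), grid_step = 1,
                         refine_step = 0.2, tol = 0.01) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  rows <- list()
  for (l0 in lambda0s) {
    sc <- sim_scenario(n = n, lambda0 = l0, beta_g = beta_g, alpha = alpha,
                       maf = maf, error = error, df = df)
    for (r in seq_len(n_reps)) {
      set.seed(make_seed(seed, r + round(1e4 * (l0 + 10))))
      d <- simulate_core(sc)
      X <- sim_design(d)
      if ("siqreg" %in% estimators) {
        est <- estimate_lambda_core(d$y, X, focals = 3L, taus = taus, B = B,
                                    interval = interval, grid_step = grid_step,
                                    refine_step = refine_step, tol = tol)[[1]]
        rows[[length(rows) + 1L]] <- tibble(
          lambda0 = l0, rep = r, estimator = "siqreg",
          lambda_hat = est$lambda_hat, uninformative = est$uninformative)
      }
      if ("warped" %in% estimators) {
        wp <- fit_warped_core(d$y, X, interval = interval, grid_step = grid_step,
                              refine_step = refine_step, tol = tol)
        rows[[length(rows) + 1L]] <- tibble(
          lambda0 = l0, rep = r, estimator = "warped",
          lambda_hat = wp$lambda_hat, uninformative = FALSE)
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  out <- reps |>
    dplyr::filter(!.data$uninformative, is.finite(.data$lambda_hat)) |>
    dplyr::group_by(.data$lambda0, .data$estimator) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_lambda_hat = mean(.data$lambda_hat),
      bias = mean(.data$lambda_hat) - .data$lambda0[1],
      mc_se = sd(.data$lambda_hat) / sqrt(dplyr::n()),
      .groups = "drop")
  attr(out, "reps") <- reps
  out
}

#' Calibration study for the heterogeneity test across scales
#'
#' Simulates purely additive latent phenotypes (no true heterogeneity) over
#' a grid of true `lambda0` and measures the rejection rate of the
#' quantile-heterogeneity test for the genotype on each analysis scale. The
#' SIQReg scale is re-estimated on every replicate from the covariate.
#'
#' @inheritParams run_recovery
#' @param scales Analysis scales: subset of
#'   `c("default", "log", "rint", "siqreg", "latent")`.
#' @param alpha_level Test size.
#' @param B_est,B_test Bootstrap sizes for scale estimation and for the
#'   heterogeneity-test covariance.
#' @param taus_test Testing quantile levels (tail-guarded by sample size).
#' @return Tibble per `(lambda0, scale)`: rejection `rate`, exact central
#'   binomial band (`band_lo`, `band_hi`) for a calibrated test, and
#'   `calibrated` flag; per-replicate p-values in attribute `"reps"`.
#' @export
run_calibration <- function(lambda0s = c(0, 0.5, 1), n = 10000L, n_reps = 500L,
                            scales = c("default", "log", "rint", "siqreg"),
                            alpha_level = 0.05, error = "gaussian", df = 3,
                            B_est = 100L, B_test = 100L,
                            taus = estimation_taus(), taus_test = testing_taus(),
                            seed = 1L, beta_g = 0.5, alpha = 1.5,
                            maf = 0.3, interval = c(-5, 5), grid_step = 1,
                            refine_step = 0.2, tol = 0.01) {
  rows <- list()
  for (l0 in lambda0s) {
    sc <- sim_scenario(n = n, lambda0 = l0, beta_g = beta_g, alpha = alpha,
                       maf = maf, error = error, df = df)
    for (r in seq_len(n_reps)) {
      set.seed(make_seed(seed, 7 * r + round(1e4 * (l0 + 10))))
      d <- simulate_core(sc)
      X <- sim_design(d)
      lam_hat <- NA_real_
      for (scl in scales) {
        yt <- switch(scl,
          default = d$y,
          latent  = d$y_latent,
          log     = log(d$y),
          rint    = rint(d$y),
          siqreg  = {
            if (is.na(lam_hat)) {
              lam_hat <- siqreg_lambda_rep(d$y, X, taus, B_est, interval,
                                           grid_step, refine_step, tol)
            }
            if (is.na(lam_hat)) NULL else as.numeric(box_cox(d$y, lam_hat))
          })
        p <- if (is.null(yt)) NA_real_ else
          het_pvalue_core(yt, X, focal = 2L, taus = taus_test, B = B_test)
        rows[[length(rows) + 1L]] <- tibble(
          lambda0 = l0, rep = r, scale = scl, p_value = p,
          lambda_hat = if (scl == "siqreg") lam_hat else NA_real_)
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  band <- binom_band(n_reps, alpha_level)
  out <- reps |>
    dplyr::group_by(.data$lambda0, .data$scale) |>
    dplyr::summarise(n_reps = sum(!is.na(.data$p_value)),
                     rate = mean(.data$p_value < alpha_level, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(band_lo = band["lower"], band_hi = band["upper"],
                  calibrated = .data$rate >= band["lower"] & .data$rate <= band["upper"])
  attr(out, "reps") <- reps
  out
}

# slim heterogeneity p-value on a prepared response and design; focal is a
# column index of X
het_pvalue_core <- function(yt, X, focal = 2L, taus = testing_taus(), B = 100L,
                            min_tail = 30) {
  n <- length(yt)
  taus <- taus[n * pmin(taus, 1 - taus) >= min_tail]
  sdt <- sd(yt)
  yt <- (yt - mean(yt)) / sdt
  core <- smqr_core(yt, X, taus)
  W <- multiplier_weights(n, B)
  arr <- smqr_boot_core(yt, core, taus, W)
  K <- length(taus)
  draws <- t(matrix(arr[focal, , ], nrow = K))
  S <- stats::cov(draws)
  suppressWarnings(wald_het_test(core$coef[focal, ], S, taus = taus,
                                 cov_df = B - 1L)$p_value)
}

#' Heterogeneity-test power over heteroscedasticity strength
#'
#' Latent errors `exp(gamma * G) * z` create genuine quantile-dependent
#' genetic effects on the latent scale; this harness measures the
#' heterogeneity test's power on a chosen analysis scale over a `gamma`
#' grid. At `gamma = 0` the power equals the test size.
#'
#' @inheritParams run_calibration
#' @param gammas Heteroscedasticity grid.
#' @param lambda0 True scale exponent held fixed.
#' @param scale Analysis scale (default `"siqreg"`, re-estimated per
#'   replicate from the covariate).
#' @return Tibble per `gamma`: rejection rate (`power`) with its binomial
#'   Monte-Carlo SE; per-replicate p-values in attribute `"reps"`.
#' @export
run_het_power <- function(gammas = c(0, 0.05, 0.1, 0.2), lambda0 = 0.5,
                          n = 10000L, n_reps = 500L, scale = "siqreg",
                          alpha_level = 0.05, B_est = 100L, B_test = 100L,
                          taus = estimation_taus(), taus_test = testing_taus(),
                          seed = 1L, beta_g = 0.5, alpha = 1.5, maf = 0.3,
                          interval = c(-5, 5), grid_step = 1,
                          refine_step = 0.2, tol = 0.01) {
  rows <- list()
  for (g in gammas) {
    sc <- sim_scenario(n = n, lambda0 = lambda0, beta_g = beta_g, alpha = alpha,
                       maf = maf, gamma = g)
    for (r in seq_len(n_reps)) {
      set.seed(make_seed(seed, 13 * r + round(1e5 * g)))
      d <- simulate_core(sc)
      X <- sim_design(d)
      yt <- switch(scale,
        latent = d$y_latent,
        default = d$y,
        log = log(d$y),
        rint = rint(d$y),
        siqreg = {
          lam <- siqreg_lambda_rep(d$y, X, taus, B_est, interval,
                                   grid_step, refine_step, tol)
          if (is.na(lam)) NULL else as.numeric(box_cox(d$y, lam))
        })
      p <- if (is.null(yt)) NA_real_ else
        het_pvalue_core(yt, X, focal = 2L, taus = taus_test, B = B_test)
      rows[[length(rows) + 1L]] <- tibble(gamma = g, rep = r, p_value = p)
    }
  }
  reps <- dplyr::bind_rows(rows)
  out <- reps |>
    dplyr::group_by(.data$gamma) |>
    dplyr::summarise(n_reps = sum(!is.na(.data$p_value)),
                     power = mean(.data$p_value < alpha_level, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(mc_se = sqrt(.data$power * (1 - .data$power) / .data$n_reps))
  attr(out, "reps") <- reps
  out
}

#' Additive-association power across scales
#'
#' Measures the power of the standard linear-regression t-test for the
#' genetic effect on the default, log, and (re-estimated per replicate)
#' SIQReg scales, over a grid of latent effect sizes. Heavy-tailed Student-t
#' latent errors by default. RINT is excluded: it is miscalibrated as a
#' heterogeneity-test scale and power on it is not comparable.
#'
#' @inheritParams run_het_power
#' @param effect_sizes Latent genetic effect grid (`beta_g` values).
#' @param scales Subset of `c("default", "log", "siqreg", "latent")`.
#' @return Tibble per `(beta_g, scale)`: rejection rate (`power`) and
#'   Monte-Carlo SE; per-replicate p-values in attribute `"reps"`.
#' @export
run_additive_power <- function(effect_sizes = c(0, 0.02, 0.05, 0.1),
                               lambda0 = 0, n = 10000L, n_reps = 500L,
                               scales = c("default", "log", "siqreg"),
                               alpha_level = 0.05, error = "gaussian", df = 3,
                               B_est = 100L, taus = estimation_taus(),
                               seed = 1L, alpha = 1, maf = 0.3,
                               interval = c(-5, 5), grid_step = 1,
                               refine_step = 0.2, tol = 0.01) {
  rows <- list()
  for (b in effect_sizes) {
    sc <- sim_scenario(n = n, lambda0 = lambda0, beta_g = b, alpha = alpha,
                       maf = maf, error = error, df = df)
    for (r in seq_len(n_reps)) {
      set.seed(make_seed(seed, 17 * r + round(1e5 * b) + round(1e3 * (lambda0 + 10))))
      d <- simulate_core(sc)
      X <- sim_design(d)
      lam_hat <- NA_real_
      for (scl in scales) {
        yt <- switch(scl,
          default = d$y,
          latent  = d$y_latent,
          log     = log(d$y),
          siqreg  = {
            lam_hat <- siqreg_lambda_rep(d$y, X, taus, B_est, interval,
                                         grid_step, refine_step, tol)
            if (is.na(lam_hat)) NULL else as.numeric(box_cox(d$y, lam_hat))
          })
        p <- if (is.null(yt)) NA_real_ else ols_t_pvalue(yt, X, 2L)
        rows[[length(rows) + 1L]] <- tibble(beta_g = b, rep = r, scale = scl,
                                            p_value = p)
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  out <- reps |>
    dplyr::group_by(.data$beta_g, .data$scale) |>
    dplyr::summarise(n_reps = sum(!is.na(.data$p_value)),
                     power = mean(.data$p_value < alpha_level, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(mc_se = sqrt(.data$power * (1 - .data$power) / .data$n_reps))
  attr(out, "reps") <- reps
  out
}

# two-sided t-test p-value for one OLS coefficient
ols_t_pvalue <- function(y, X, j) {
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  XtXinv_jj <- chol2inv(chol(crossprod(X)))[j, j]
  se <- sqrt(rss / df * XtXinv_jj)
  2 * stats::pt(-abs(fit$coefficients[j] / se), df)
}

#' Per-quantile effect profile shape across scales
#'
#' Fits the genotype's per-quantile effect profile on each scale for one
#' simulated dataset and reports the bootstrap z-score of the linear trend
#' of effect versus quantile level: near zero where the scale is additive,
#' away from zero where the scale distorts an additive effect.
#'
#' @inheritParams run_calibration
#' @param lambda0 True scale exponent (default 0: latent = log scale).
#' @param scales Scales to profile.
#' @param B Bootstrap replicates for the trend SE.
#' @return Tibble per scale: trend `slope`, `se`, `z`, and the SIQReg
#'   `lambda_hat` where applicable.
#' @export
run_profile_shapes <- function(lambda0 = 0, n = 10000L,
                               scales = c("latent", "siqreg", "log", "default", "rint"),
                               taus = estimation_taus(), B = 200L, B_est = 100L,
                               seed = 1L, beta_g = 0.5, alpha = 0.5, maf = 0.3,
                               interval = c(-5, 5), tol = 0.01) {
  sc <- sim_scenario(n = n, lambda0 = lambda0, beta_g = beta_g, alpha = alpha,
                     maf = maf)
  set.seed(make_seed(seed, 1L))
  d <- simulate_core(sc)
  X <- sim_design(d)
  lam_hat <- NA_real_
  rows <- list()
  for (scl in scales) {
    yt <- switch(scl,
      latent = d$y_latent,
      default = d$y,
      log = log(d$y),
      rint = rint(d$y),
      siqreg = {
        lam_hat <- siqreg_lambda_rep(d$y, X, estimation_taus(), B_est,
                                     interval, 1, 0.2, tol)
        as.numeric(box_cox(d$y, lam_hat))
      })
    sdt <- sd(yt)
    ys <- (yt - mean(yt)) / sdt
    core <- smqr_core(ys, X, taus)
    W <- multiplier_weights(n, B)
    arr <- smqr_boot_core(ys, core, taus, W)
    K <- length(taus)
    betas <- core$coef[2L, ]
    draws <- t(matrix(arr[2L, , ], nrow = K))
    tr <- profile_trend(betas, taus, stats::cov(draws))
    rows[[length(rows) + 1L]] <- tibble(
      scale = scl, slope = tr$slope, se = tr$se, z = tr$z,
      lambda_hat = if (scl == "siqreg") lam_hat else NA_real_)
  }
  dplyr::bind_rows(rows)
}

#' Linear trend of a per-quantile effect profile
#'
#' Least-squares slope of effect estimates against quantile level, with its
#' standard error propagated from the effects' covariance (the slope is a
#' linear contrast of the effects).
#'
#' @param betas Per-quantile effect estimates.
#' @param taus Quantile levels.
#' @param cov Covariance matrix of `betas`.
#' @return List with `slope`, `se`, `z`.
#' @export
profile_trend <- function(betas, taus, cov) {
  ct <- taus - mean(taus)
  w <- ct / sum(ct^2)
  slope <- sum(w * betas)
  se <- sqrt(drop(t(w) %*% cov %*% w))
  list(slope = slope, se = se, z = slope / se)
}
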