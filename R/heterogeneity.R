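#' Successive-difference contrast matrix
#'
#' The (K-1) x K matrix with rows `(1, -1, 0, ...)`, `(0, 1, -1, ...)`, ...
#' used to contrast a predictor's effects at adjacent quantile levels. Full
#' row rank K-1.
#'
#' @param K Number of quantile levels (>= 2).
#' @return (K-1) x K numeric matrix.
#' @export
contrast_matrix <- function(K) {
  K <- as.integer(K)
  if (K < 2L) abort("contrast_matrix() needs K >= 2.")
  A <- matrix(0, K - 1L, K)
  A[cbind(seq_len(K - 1L), seq_len(K - 1L))] <- 1
  A[cbind(seq_len(K - 1L), seq_len(K - 1L) + 1L)] <- -1
  A
}

# Moore-Penrose pseudo-inverse via eigendecomposition (symmetric input)
sym_pinv <- function(M, tol = NULL) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tol <- tol %||% (max(abs(e$values)) * max(dim(M)) * .Machine$double.eps)
  keep <- e$values > tol
  rank <- sum(keep)
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(inv = inv, rank = rank)
}

#' Wald test of quantile-effect heterogeneity
#'
#' Tests the null that a predictor's effect is identical at all K quantile
#' levels: `T = (A b)' (A S A')^{-1} (A b)` with `A` the successive-difference
#' contrast; under the null T is asymptotically chi-squared with K-1 degrees
#' of freedom. If `A S A'` is numerically singular, a Moore-Penrose
#' pseudo-inverse is used with a warning and the rank reported as the
#' effective degrees of freedom.
#'
#' When `cov` is estimated from a finite number of bootstrap replicates, the
#' chi-squared reference is anticonservative (the inverted covariance is
#' noisy). Supplying `cov_df` (the replicate count minus one) switches to the
#' Hotelling-type F calibration
#' `T * (cov_df - K + 2) / (cov_df * (K - 1)) ~ F(K-1, cov_df - K + 2)`,
#' which converges to the chi-squared reference as the replicate count grows.
#'
#' @param betas Length-K vector of per-quantile effect estimates.
#' @param cov K x K covariance matrix of `betas` (e.g. from
#'   [bootstrap_cov()]).
#' @param taus Optional quantile levels, carried into the result.
#' @param scale_tag Optional label for the phenotype scale tested.
#' @param cov_df Degrees of freedom of the covariance estimate (bootstrap
#'   replicates minus one); `NULL` uses the asymptotic chi-squared reference.
#' @return A `het_result` object (statistic, df, p_value, betas, contrast).
#' @examples
#' wald_het_test(c(0, 1), diag(2))  # T = 0.5 on 1 df
#' @export
wald_het_test <- function(betas, cov, taus = NULL, scale_tag = NULL,
                          cov_df = NULL) {
  K <- length(betas)
  if (K < 2L) abort("wald_het_test() needs at least two quantile levels.")
  stopifnot(is.matrix(cov), nrow(cov) == K, ncol(cov) == K)
  A <- contrast_matrix(K)
  d <- drop(A %*% betas)
  M <- A %*% cov %*% t(A)
  df <- K - 1L
  solved <- tryCatch(list(inv = solve(M), rank = K - 1L), error = function(e) NULL)
  if (is.null(solved) || !all(is.finite(solved$inv)) ||
      kappa(M, exact = FALSE) > 1e12) {
    solved <- sym_pinv(M)
    df <- solved$rank
    warn(sprintf("wald_het_test(): contrast covariance singular; pseudo-inverse used, effective df = %d.", df))
  }
  statistic <- max(0, drop(t(d) %*% solved$inv %*% d))
  if (!is.null(cov_df)) {
    df2 <- cov_df - df + 1
    if (df2 < 1) abort("wald_het_test(): cov_df too small for the contrast dimension.")
    p_value <- stats::pf(statistic * df2 / (cov_df * df), df, df2,
                         lower.tail = FALSE)
  } else {
    p_value <- pchisq(statistic, df = df, lower.tail = FALSE)
  }
  structure(
    list(statistic = statistic, df = df,
         p_value = p_value,
         betas = betas, taus = taus, contrast = A,
         scale_tag = scale_tag %||% NA_character_, se = NULL),
    class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat("Quantile-heterogeneity Wald test",
      if (!is.na(x$scale_tag)) sprintf(" (scale: %s)", x$scale_tag), "\n", sep = "")
  cat(sprintf("T = %.4g on %d df, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.het_result <- function(x, ...) {
  tibble(tau = x$taus %||% seq_along(x$betas), beta = x$betas,
         se = x$se %||% rep(NA_real_, length(x$betas)))
}

#' @exportS3Method generics::glance
glance.het_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         scale = x$scale_tag, k_taus = length(x$betas))
}

#' Scan a predictor for quantile-dependent effects on a chosen scale
#'
#' Transforms the phenotype onto the requested scale, fits smoothed quantile
#' regression of it on the predictor (plus covariates) at the testing quantile
#' levels, estimates the predictor coefficients' covariance across levels by
#' multiplier bootstrap, and applies [wald_het_test()].
#'
#' Extreme levels with fewer than `min_tail` expected observations beyond
#' them (`n * min(tau, 1 - tau) < min_tail`) are dropped with a warning.
#'
#' @inheritParams fit_quantile
#' @param predictor Name of the focal predictor column (genotype dosage, PGS,
#'   any numeric predictor).
#' @param covariates Optional character vector of covariate columns, always
#'   included in the design.
#' @param scale Phenotype scale to test on: `"default"`, `"log"`, `"rint"`,
#'   `"boxcox"` (requires `lambda`), or `"latent"` (no transformation; for
#'   simulated data already on the latent scale).
#' @param lambda Box-Cox exponent when `scale = "boxcox"`.
#' @param taus Testing quantile levels; default [testing_taus()].
#' @param B Bootstrap replicates for the coefficient covariance.
#' @param seed Integer seed for the bootstrap.
#' @param min_tail Minimum expected tail count per tested level (default 30).
#' @param positivity Passed to [box_cox()] for positive-scale transforms.
#' @return A `het_result` with per-quantile effects and bootstrap SEs.
#' @export
quantile_het_scan <- function(data, phenotype, predictor, covariates = NULL,
                              scale = c("default", "log", "rint", "boxcox", "latent"),
                              lambda = NULL, taus = testing_taus(),
                              B = 200L, seed = NULL, min_tail = 30,
                              positivity = "error") {
  scale <- match.arg(scale)
  cols <- c(phenotype, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (sd(data[[predictor]]) == 0) abort("`predictor` has zero variance.")
  n <- nrow(data)
  keep <- n * pmin(taus, 1 - taus) >= min_tail
  if (!all(keep)) {
    warn(sprintf("quantile_het_scan(): dropped %d extreme quantile level(s) with expected tail count < %g: %s",
                 sum(!keep), min_tail, paste(taus[!keep], collapse = ", ")))
    taus <- taus[keep]
  }
  if (length(taus) < 2L) abort("Fewer than two usable quantile levels after the tail guard.")
  d <- as_tibble(data)
  d[[".y_scaled"]] <- as.numeric(apply_scale(d[[phenotype]], scale, lambda, positivity))
  fit <- fit_quantile(d, ".y_scaled", c(predictor, covariates), taus = taus)
  S <- bootstrap_cov(fit, predictor, B = B, seed = seed)
  betas <- fit$coefficients[match(predictor, fit$terms), ]
  out <- wald_het_test(betas, S, taus = taus,
                       scale_tag = if (scale == "boxcox")
                         sprintf("boxcox(%.3f)", lambda) else scale,
                       cov_df = B - 1L)
  out$se <- sqrt(diag(S))
  out$fit <- fit
  out
}
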