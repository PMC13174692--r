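# ---- internal engine --------------------------------------------------------
# All heavy work happens at matrix level so the simulation harnesses can call
# it in tight loops without data-frame overhead.

# Evaluate the SIQReg Wald objective at one lambda for one or more focal
# covariates. The QR fit and the multiplier bootstrap are shared across
# focals: only the coefficient extraction differs.
#
# Returns: list(obj = named vector, uninformative = logical vector,
#               init_std = warm-start matrix, details = per-focal list)
siqreg_eval <- function(lambda, y, X, focals, taus, W,
                        init_std = NULL, positivity = "error") {
  yt <- as.numeric(box_cox(y, lambda, positivity = positivity))
  K <- length(taus)
  degenerate <- function() {
    nf <- length(focals)
    list(obj = rep(NA_real_, nf), uninformative = rep(TRUE, nf),
         init_std = init_std,
         details = rep(list(list(alpha = rep(NA_real_, K), abar = NA_real_,
                                 r_star = rep(NA_real_, K))), nf))
  }
  # extreme candidates can overflow the power transform outright
  if (!all(is.finite(yt))) return(degenerate())
  mu <- mean(yt)
  sdt <- sd(yt)
  if (!is.finite(sdt) || sdt == 0) return(degenerate())
  yt <- (yt - mu) / sdt   # objective is ratio-based, hence scale-free
  # resolution guard: an extreme candidate lambda can compress the central
  # mass of the transformed phenotype into less than a couple of smoothing
  # bandwidths; decile coefficients are then artificially homogeneous and the
  # objective spuriously small. Such candidates are degenerate, not minima.
  h <- bandwidth_rule(length(yt), ncol(X))
  span <- diff(as.numeric(quantile(yt, c(min(taus), max(taus)))))
  if (span < 2 * h) return(degenerate())
  core <- smqr_core(yt, X, taus, init_std = init_std)
  if (!all(is.finite(core$coef_std))) return(degenerate())
  arr <- smqr_boot_core(yt, core, taus, W)
  obj <- rep(NA_real_, length(focals))
  uninf <- rep(FALSE, length(focals))
  details <- vector("list", length(focals))
  for (f in seq_along(focals)) {
    j <- focals[f]
    alpha <- core$coef[j, ]
    abar <- mean(alpha)
    draws <- t(matrix(arr[j, , ], nrow = K))      # B x K
    if (!all(is.finite(draws))) {
      uninf[f] <- TRUE
      details[[f]] <- list(alpha = alpha, abar = abar, r_star = rep(NA_real_, K))
      next
    }
    abar_b <- rowMeans(draws)
    abar_se <- sd(abar_b)
    if (!is.finite(abar_se) || abar_se == 0 || abs(abar) / abar_se < 2) {
      uninf[f] <- TRUE
      details[[f]] <- list(alpha = alpha, abar = abar, r_star = rep(NA_real_, K))
      next
    }
    r <- 1 - alpha / abar
    r_b <- 1 - draws / abar_b                      # B x K replicate residuals
    # r sums to zero structurally: drop the last coordinate and invert the
    # (K-1) x (K-1) bootstrap covariance (generalized inverse as fallback)
    S1 <- stats::cov(r_b[, -K, drop = FALSE])
    r1 <- r[-K]
    q <- tryCatch(drop(t(r1) %*% solve(S1, r1)), error = function(e) NA_real_)
    if (!is.finite(q) || q < 0) q <- drop(t(r1) %*% sym_pinv(S1)$inv %*% r1)
    obj[f] <- q
    details[[f]] <- list(alpha = alpha, abar = abar, r_star = r, sigma = stats::cov(r_b))
  }
  list(obj = obj, uninformative = uninf, init_std = core$coef_std, details = details)
}

# Hierarchical minimization of a memoized 1-d objective: coarse grid, finer
# grid around the coarse argmin, then golden-section refinement.
search_lambda <- function(f, interval = c(-5, 5), grid_step = 1, refine_step = 0.2,
                          tol = 0.005) {
  lo <- interval[1]; hi <- interval[2]
  grid1 <- seq(lo, hi, by = grid_step)
  v1 <- vapply(grid1, f, numeric(1))
  if (all(is.na(v1))) return(list(lambda = NA_real_, ok = FALSE))
  l1 <- grid1[which.min(v1)]
  grid2 <- seq(max(lo, l1 - grid_step), min(hi, l1 + grid_step), by = refine_step)
  v2 <- vapply(grid2, f, numeric(1))
  l2 <- grid2[which.min(v2)]
  a <- max(lo, l2 - refine_step); b <- min(hi, l2 + refine_step)
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (isTRUE(f1 <= f2) || is.na(f2)) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  list(lambda = (a + b) / 2, ok = TRUE)
}

# Per-covariate lambda estimation at matrix level. focals: column indices of
# X. Common random numbers: one weight matrix W shared by every lambda
# candidate so the objective curve is smooth in lambda (disable by passing
# fresh weights per call at your peril).
estimate_lambda_core <- function(y, X, focals, taus = estimation_taus(),
                                 B = 100L, seed = NULL, interval = c(-5, 5),
                                 grid_step = 1, refine_step = 0.2, tol = 0.005,
                                 positivity = "error", crn = TRUE) {
  n <- length(y)
  W <- multiplier_weights(n, B, seed)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(lambda, focal_set) {
    key <- sprintf("%.6f", lambda)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (!crn) W <- multiplier_weights(n, B)
    # warm start from the nearest already-evaluated candidate: solutions vary
    # smoothly in lambda, while the most recent evaluation can be far away
    done <- as.numeric(ls(cache))
    done <- done[vapply(done, function(l)
      !is.null(cache[[sprintf("%.6f", l)]]$init_std), logical(1))]
    init <- NULL
    if (length(done)) {
      near <- cache[[sprintf("%.6f", done[which.min(abs(done - lambda))])]]
      init <- near$init_std
    }
    res <- siqreg_eval(lambda, y, X, focal_set, taus, W,
                       init_std = init, positivity = positivity)
    cache[[key]] <- res
    res
  }
  out <- vector("list", length(focals))
  # coarse stage shared across focals
  grid1 <- seq(interval[1], interval[2], by = grid_step)
  for (l in grid1) eval_at(l, focals)
  for (f in seq_along(focals)) {
    fv <- function(l) eval_at(l, focals)$obj[f]
    v1 <- vapply(grid1, fv, numeric(1))
    if (all(is.na(v1))) {
      out[[f]] <- list(lambda_hat = NA_real_, uninformative = TRUE,
                       boundary = FALSE, trace = NULL)
      next
    }
    l1 <- grid1[which.min(v1)]
    res <- search_lambda(fv, interval = c(max(interval[1], l1 - grid_step),
                                          min(interval[2], l1 + grid_step)),
                         grid_step = refine_step, refine_step = refine_step / 2,
                         tol = tol)
    lam <- res$lambda
    ev <- eval_at(lam, focals)
    trace_l <- sort(as.numeric(ls(cache)))
    trace <- tibble(
      lambda = trace_l,
      objective = vapply(trace_l, function(l) cache[[sprintf("%.6f", l)]]$obj[f],
                         numeric(1)))
    out[[f]] <- list(
      lambda_hat = lam,
      uninformative = ev$uninformative[f],
      boundary = isTRUE(abs(lam - interval[1]) < 2 * tol ||
                          abs(lam - interval[2]) < 2 * tol),
      objective = ev$obj[f],
      trace = trace,
      details = ev$details[[f]])
  }
  out
}

# deterministic sub-seed derivation, kept under 2^31
make_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

# ---- exported surface -------------------------------------------------------

#' SIQReg Wald objective at a candidate scale
#'
#' Fits smoothed quantile regression of `box_cox(y, lambda)` on all
#' covariates at the estimation quantile levels, forms the focal covariate's
#' relative coefficient residuals `r*_k = 1 - alpha_k / mean(alpha)`, and
#' returns the Wald quadratic form `r*' Sigma^- r*` with `Sigma` estimated by
#' multiplier bootstrap. The residuals sum to zero by construction, so a
#' rank-(K-1) inverse is used.
#'
#' @inheritParams fit_quantile
#' @param covariates Character vector of covariate columns (all enter the
#'   design).
#' @param focal Focal covariate whose effect profile defines the objective;
#'   default the first covariate.
#' @param lambda Candidate Box-Cox exponent.
#' @param B Bootstrap replicates for `Sigma`.
#' @param seed Integer seed for the bootstrap weights.
#' @param positivity Passed to [box_cox()].
#' @return Nonnegative objective value (`NA` with attribute
#'   `uninformative = TRUE` when the focal covariate's mean effect is not
#'   distinguishable from zero), with attributes `r_star` and `alpha`.
#' @export
wald_objective <- function(data, phenotype, covariates, focal = covariates[1],
                           lambda, taus = estimation_taus(), B = 200L,
                           seed = NULL, positivity = "error") {
  y <- as.numeric(data[[phenotype]])
  X <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
  j <- match(focal, covariates) + 1L
  if (is.na(j)) abort("`focal` must be one of `covariates`.")
  W <- multiplier_weights(length(y), B, seed)
  res <- siqreg_eval(lambda, y, X, j, taus, W, positivity = positivity)
  out <- res$obj[1]
  attr(out, "uninformative") <- res$uninformative[1]
  attr(out, "r_star") <- res$details[[1]]$r_star
  attr(out, "alpha") <- res$details[[1]]$alpha
  out
}

#' Estimate the Box-Cox scale from one focal covariate
#'
#' Minimizes the SIQReg Wald objective over `lambda` in the search interval:
#' a coarse grid, a finer grid around its minimum, then golden-section
#' refinement. The bootstrap uses common random numbers across candidate
#' `lambda` so the objective curve is smooth and the argmin well behaved.
#'
#' @inheritParams wald_objective
#' @param interval Search interval for `lambda` (default `c(-5, 5)`).
#' @param grid_step,refine_step,tol Search controls: coarse grid step, fine
#'   grid step, and golden-section width tolerance in `lambda`.
#' @param crn Use common random numbers across candidates (recommended).
#' @return A list: `lambda_hat`, logical `boundary` and `uninformative`
#'   flags, and `trace` (tibble of evaluated `(lambda, objective)` pairs).
#' @export
estimate_lambda_one <- function(data, phenotype, covariates, focal = covariates[1],
                                taus = estimation_taus(), B = 200L, seed = NULL,
                                interval = c(-5, 5), grid_step = 1,
                                refine_step = 0.2, tol = 0.005,
                                positivity = "error", crn = TRUE) {
  y <- as.numeric(data[[phenotype]])
  X <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
  j <- match(focal, covariates) + 1L
  if (is.na(j)) abort("`focal` must be one of `covariates`.")
  res <- estimate_lambda_core(y, X, j, taus = taus, B = B, seed = seed,
                              interval = interval, grid_step = grid_step,
                              refine_step = refine_step, tol = tol,
                              positivity = positivity, crn = crn)[[1]]
  if (res$boundary)
    warn(sprintf("estimate_lambda_one(): optimum on the search boundary (lambda = %.3f).",
                 res$lambda_hat))
  res
}

#' Inverse-variance meta-analysis of per-covariate scale estimates
#'
#' Fixed-effect inverse-variance pooling of per-covariate `lambda` estimates,
#' with Cochran's Q reported as a cross-covariate heterogeneity diagnostic.
#'
#' @param estimates Data frame with columns `lambda_hat` and `se` (one row
#'   per informative covariate). Rows with non-finite entries are dropped.
#' @return One-row tibble: `lambda0`, `se`, `q`, `q_df`, `q_p`,
#'   `n_covariates`.
#' @examples
#' meta_analyze(tibble::tibble(lambda_hat = c(0, 1), se = c(1, 0.5)))
#' @export
meta_analyze <- function(estimates) {
  est <- estimates[is.finite(estimates$lambda_hat) & is.finite(estimates$se) &
                     estimates$se > 0, , drop = FALSE]
  if (nrow(est) == 0)
    abort("meta_analyze(): no informative covariate estimates to pool.")
  w <- 1 / est$se^2
  lam <- sum(w * est$lambda_hat) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (est$lambda_hat - lam)^2)
  q_df <- nrow(est) - 1L
  tibble(lambda0 = lam, se = se, q = q, q_df = q_df,
         q_p = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
         n_covariates = nrow(est))
}

#' Subsampling standard error and confidence interval for the scale estimate
#'
#' Splits the sample into `R` disjoint subsamples, reruns the full
#' per-covariate estimation and meta-analysis on each, and uses the spread of
#' subsample estimates: `SE = sd(subsample estimates) / sqrt(R)`, with a
#' normal-quantile interval around `center`.
#'
#' @inheritParams estimate_lambda_one
#' @param R Number of disjoint subsamples (>= 2).
#' @param level Confidence level (default 0.95).
#' @param center Point estimate the interval is built around (full-sample
#'   meta-analyzed estimate). If `NULL`, the mean of subsample estimates.
#' @return List: `se`, `ci_low`, `ci_high`, `per_covariate_se` (named), and
#'   `subsamples` (tibble of per-subsample, per-covariate estimates).
#' @export
subsample_ci <- function(data, phenotype, covariates, R = 10L, level = 0.95,
                         seed = NULL, center = NULL, taus = estimation_taus(),
                         B = 200L, interval = c(-5, 5), grid_step = 1,
                         refine_step = 0.2, tol = 0.005, positivity = "error") {
  if (R < 2) abort("subsample_ci() needs R >= 2 disjoint subsamples.")
  n <- nrow(data)
  y <- as.numeric(data[[phenotype]])
  X <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
  focals <- seq_along(covariates) + 1L
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  assignment <- sample(rep_len(seq_len(R), n))
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    idx <- which(assignment == r)
    est <- estimate_lambda_core(y[idx], X[idx, , drop = FALSE], focals,
                                taus = taus, B = B, seed = make_seed(seed, r),
                                interval = interval, grid_step = grid_step,
                                refine_step = refine_step, tol = tol,
                                positivity = positivity)
    rows[[r]] <- tibble(subsample = r, covariate = covariates,
                        lambda_hat = vapply(est, `[[`, numeric(1), "lambda_hat"),
                        uninformative = vapply(est, `[[`, logical(1), "uninformative"))
  }
  subs <- dplyr::bind_rows(rows)
  per_cov <- subs |>
    dplyr::filter(!.data$uninformative, is.finite(.data$lambda_hat)) |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(se = sd(.data$lambda_hat) / sqrt(dplyr::n()), .groups = "drop")
  per_covariate_se <- setNames(per_cov$se, per_cov$covariate)
  # meta-analyze within each subsample using equal weights (per-covariate SEs
  # are not available within a single subsample pass), then pool the spread
  meta_by_sub <- subs |>
    dplyr::filter(!.data$uninformative, is.finite(.data$lambda_hat)) |>
    dplyr::group_by(.data$subsample) |>
    dplyr::summarise(lambda0 = mean(.data$lambda_hat), .groups = "drop")
  se <- sd(meta_by_sub$lambda0) / sqrt(nrow(meta_by_sub))
  center <- center %||% mean(meta_by_sub$lambda0)
  z <- qnorm(1 - (1 - level) / 2)
  list(se = se, ci_low = center - z * se, ci_high = center + z * se,
       per_covariate_se = per_covariate_se, subsamples = subs)
}

#' Estimate the SIQReg phenotype scale
#'
#' End-to-end scale estimation: per-covariate minimization of the
#' quantile-heterogeneity Wald objective at the estimation deciles,
#' subsampling standard errors, inverse-variance meta-analysis across
#' informative covariates, a z-test of the default scale (`H0: lambda0 = 1`),
#' and Anderson-Darling residual-normality diagnostics on the default versus
#' estimated scales.
#'
#' @inheritParams subsample_ci
#' @param B Bootstrap replicates per objective evaluation.
#' @return A `scale_estimate` object; see [tidy.scale_estimate()] and
#'   [glance.scale_estimate()].
#' @export
estimate_scale <- function(data, phenotype, covariates, taus = estimation_taus(),
                           B = 200L, R = 10L, level = 0.95, seed = NULL,
                           interval = c(-5, 5), grid_step = 1, refine_step = 0.2,
                           tol = 0.005, positivity = "error") {
  stopifnot(length(covariates) >= 1)
  cols <- c(phenotype, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (anyNA(data[cols])) abort("`data` contains missing values in used columns.")
  y <- as.numeric(data[[phenotype]])
  X <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
  focals <- seq_along(covariates) + 1L

  full <- estimate_lambda_core(y, X, focals, taus = taus, B = B,
                               seed = make_seed(seed, 0L), interval = interval,
                               grid_step = grid_step, refine_step = refine_step,
                               tol = tol, positivity = positivity)
  per_cov <- tibble(
    covariate = covariates,
    lambda_hat = vapply(full, `[[`, numeric(1), "lambda_hat"),
    objective = vapply(full, function(x) x$objective %||% NA_real_, numeric(1)),
    uninformative = vapply(full, `[[`, logical(1), "uninformative"),
    boundary = vapply(full, `[[`, logical(1), "boundary"))
  if (all(per_cov$uninformative))
    abort("estimate_scale(): every covariate is uninformative (|mean effect|/SE < 2); cannot estimate the scale.")

  ss <- subsample_ci(data, phenotype, covariates, R = R, level = level,
                     seed = make_seed(seed, 1L), center = NULL, taus = taus,
                     B = B, interval = interval, grid_step = grid_step,
                     refine_step = refine_step, tol = tol, positivity = positivity)
  per_cov$se <- unname(ss$per_covariate_se[per_cov$covariate])

  informative <- per_cov[!per_cov$uninformative, , drop = FALSE]
  meta <- if (any(is.finite(informative$se)) && nrow(informative) > 1) {
    meta_analyze(informative)
  } else {
    tibble(lambda0 = informative$lambda_hat[1],
           se = informative$se[1] %||% NA_real_,
           q = NA_real_, q_df = 0L, q_p = NA_real_, n_covariates = 1L)
  }
  lambda0 <- meta$lambda0
  se <- ss$se
  z <- qnorm(1 - (1 - level) / 2)

  z1 <- (lambda0 - 1) / se
  ad_default <- anderson_darling(ols_residuals(y, X))
  ad_siqreg <- anderson_darling(ols_residuals(
    as.numeric(box_cox(y, lambda0, positivity = positivity)), X))

  structure(
    list(lambda_hat = lambda0, se = se,
         ci_low = lambda0 - z * se, ci_high = lambda0 + z * se, level = level,
         per_covariate = per_cov,
         meta = meta,
         test_default_scale = list(z = z1, p = 2 * pnorm(-abs(z1))),
         ad = c(default = ad_default, siqreg = ad_siqreg),
         objective_trace = purrr::map2(covariates, full,
                                       ~ dplyr::mutate(.y$trace %||% tibble(),
                                                       covariate = .x)),
         subsamples = ss$subsamples,
         taus = taus, B = B, R = R, seed = seed, interval = interval,
         phenotype = phenotype, covariates = covariates, n = length(y)),
    class = "scale_estimate")
}

ols_residuals <- function(y, X) {
  y - X %*% lm.fit(X, y)$coefficients
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat("SIQReg scale estimate\n")
  cat(sprintf("  lambda0 = %.4f (SE %.4f, %d%% CI [%.4f, %.4f])\n",
              x$lambda_hat, x$se, round(100 * x$level), x$ci_low, x$ci_high))
  cat(sprintf("  H0: lambda0 = 1: z = %.3f, p = %.3g\n",
              x$test_default_scale$z, x$test_default_scale$p))
  cat(sprintf("  Anderson-Darling residual A^2: default %.2f -> siqreg %.2f\n",
              x$ad["default"], x$ad["siqreg"]))
  cat(sprintf("  %d covariate(s), %d informative\n", nrow(x$per_covariate),
              sum(!x$per_covariate$uninformative)))
  invisible(x)
}

#' Tidy per-covariate scale estimates
#'
#' @param x A `scale_estimate`.
#' @param ... Unused.
#' @return Tibble with one row per covariate: `covariate`, `lambda_hat`,
#'   `se`, `objective`, `uninformative`, `boundary`.
#' @exportS3Method generics::tidy
tidy.scale_estimate <- function(x, ...) x$per_covariate

#' One-row summary of a scale estimate
#'
#' @inheritParams tidy.scale_estimate
#' @return One-row tibble: pooled `lambda_hat`, `se`, CI bounds, z/p for
#'   `H0: lambda0 = 1`, Anderson-Darling statistics on both scales, Cochran's
#'   Q, and sizes.
#' @exportS3Method generics::glance
glance.scale_estimate <- function(x, ...) {
  tibble(lambda_hat = x$lambda_hat, se = x$se, ci_low = x$ci_low,
         ci_high = x$ci_high, z_default = x$test_default_scale$z,
         p_default = x$test_default_scale$p,
         ad_default = x$ad["default"], ad_siqreg = x$ad["siqreg"],
         q = x$meta$q, q_p = x$meta$q_p,
         n = x$n, n_covariates = nrow(x$per_covariate), r_subsamples = x$R)
}
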