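#' Quantile-level defaults
#'
#' The two canonical quantile-level sets: deciles `0.1, ..., 0.9` for scale
#' (lambda) estimation, and a nine-level spread reaching into the tails for
#' heterogeneity testing. The two sets serve different purposes and are kept
#' separate throughout.
#'
#' @return Numeric vector of quantile levels.
#' @export
estimation_taus <- function() seq(0.1, 0.9, by = 0.1)

#' @rdname estimation_taus
#' @export
testing_taus <- function() c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)

#' Quantile-regression check loss
#'
#' The asymmetric absolute loss \eqn{\rho_\tau(u) = u(\tau - 1\{u<0\})},
#' weighting positive residuals by \eqn{\tau} and negative by \eqn{1-\tau}.
#'
#' @param u Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Nonnegative numeric vector, zero iff `u == 0`.
#' @export
check_loss <- function(u, tau) {
  stopifnot(tau > 0, tau < 1)
  u * (tau - (u < 0))
}

#' Convolution-smoothed check loss (Gaussian kernel)
#'
#' The check loss convolved with a Gaussian kernel of bandwidth `h`,
#' \eqn{l_h(u) = \int \rho_\tau(v) K_h(v-u)\,dv}. For the Gaussian kernel this
#' has the closed form \eqn{\tau u - u\Phi(-u/h) + h\phi(u/h)}; it is convex,
#' twice continuously differentiable, and converges to [check_loss()] as
#' `h -> 0`. Its derivative in `u` is \eqn{\tau - \Phi(-u/h)}.
#'
#' @inheritParams check_loss
#' @param h Positive bandwidth.
#' @return Nonnegative numeric vector.
#' @export
smoothed_loss <- function(u, tau, h) {
  stopifnot(tau > 0, tau < 1)
  if (!is.numeric(h) || length(h) != 1L || h <= 0) abort("`h` must be a positive scalar.")
  tau * u - u * pnorm(-u / h) + h * dnorm(u / h)
}

#' Bandwidth rule for smoothed quantile regression
#'
#' `h = ((p + log n) / n)^(2/5)`, the recommended rate-optimal choice
#' (exponent 2/5 within the admissible range `[1/4, 1/2]`).
#'
#' @param n Sample size.
#' @param p Number of regression coefficients (including the intercept).
#' @return Positive bandwidth.
#' @export
bandwidth_rule <- function(n, p) {
  stopifnot(p >= 1)
  if (n <= p) abort("bandwidth_rule() requires n > p.")
  ((p + log(n)) / n)^(2 / 5)
}

# ---- internal matrix-level engine ------------------------------------------

# standardize non-intercept columns; X must have an all-ones first column
smqr_standardize <- function(X) {
  p <- ncol(X)
  mx <- rep(0, p)
  sx <- rep(1, p)
  if (p > 1L) {
    for (j in 2:p) {
      mx[j] <- mean(X[, j])
      s <- sd(X[, j])
      sx[j] <- if (s > 0) s else 1
      X[, j] <- (X[, j] - mx[j]) / sx[j]
    }
  }
  list(X = X, mx = mx, sx = sx)
}

# map standardized-scale coefficients (p x K or p x K x B) back to raw scale
smqr_unstandardize <- function(coef, mx, sx) {
  p <- nrow(coef)
  if (p == 1L) return(coef)
  if (length(dim(coef)) == 2L) {
    slopes <- coef[-1, , drop = FALSE] / sx[-1]
    coef[1, ] <- coef[1, ] - colSums(slopes * mx[-1])
    coef[-1, ] <- slopes
  } else {
    K <- dim(coef)[2]
    for (b in seq_len(dim(coef)[3])) {
      slopes <- matrix(coef[-1, , b], nrow = p - 1L, ncol = K) / sx[-1]
      coef[1, , b] <- coef[1, , b] - colSums(slopes * mx[-1])
      coef[-1, , b] <- slopes
    }
  }
  coef
}

# core solver on raw inputs; returns standardized-scale fit plus metadata so
# bootstrap replicates can reuse the standardization and warm starts
smqr_core <- function(y, X, taus, h = NULL, tol = NULL, max_iter = 500L,
                      init_std = NULL, w = NULL) {
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  if (is.unsorted(taus, strictly = TRUE) || any(taus <= 0) || any(taus >= 1))
    abort("`taus` must be strictly increasing and inside (0, 1).")
  if (qr(X)$rank < p) abort("Design matrix is rank deficient.")
  h <- h %||% bandwidth_rule(n, p)
  tol <- tol %||% (1e-5 * max(sd(y), .Machine$double.eps))
  std <- smqr_standardize(X)
  # the dimensionless bandwidth rule assumes a unit-scale RESIDUAL; smoothing
  # acts on residuals, so h is scaled by the least-squares residual sd (not
  # the marginal sd, which over-smooths when the signal dominates). Scaling
  # by a response-equivariant dispersion also makes coefficients exactly
  # equivariant to rescaling the response.
  ols <- lm.fit(std$X, y)
  s_y <- sd(ols$residuals)
  if (!is.finite(s_y) || s_y == 0) s_y <- max(sd(y), .Machine$double.eps)
  ys <- y / s_y
  if (is.null(init_std)) {
    init_s <- matrix(ols$coefficients / s_y, nrow = p, ncol = length(taus))
  } else {
    init_s <- init_std / s_y
  }
  w <- w %||% rep(1, n)
  fit <- fit_smqr_cpp(std$X, ys, taus, h, w, init_s, tol / s_y,
                      as.integer(max_iter))
  coef_std <- fit$coef * s_y
  list(coef_std = coef_std, iters = fit$iters, converged = fit$converged,
       X_std = std$X, mx = std$mx, sx = std$sx, h = h, tol = tol, s_y = s_y,
       coef = smqr_unstandardize(coef_std, std$mx, std$sx))
}

# exponential multiplier weights, n x B, threaded through the caller's RNG
multiplier_weights <- function(n, B, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  matrix(rexp(n * B), nrow = n, ncol = B)
}

# multiplier-bootstrap coefficient array (p x K x B) on the raw scale;
# replicates are warm-started at the full-data solution and solved to a
# looser tolerance (coefficient effect far below bootstrap sampling noise)
smqr_boot_core <- function(y, core, taus, W, max_iter = 100L) {
  s_y <- core$s_y
  arr <- boot_smqr_cpp(core$X_std, y / s_y, taus, core$h, W,
                       core$coef_std / s_y, core$tol * 20 / s_y,
                       as.integer(max_iter))
  smqr_unstandardize(arr * s_y, core$mx, core$sx)
}

# ---- user-facing fit --------------------------------------------------------

#' Fit convolution-smoothed quantile regression
#'
#' Fits linear quantile regression at each requested quantile level by
#' minimizing the Gaussian-convolution-smoothed check loss with
#' Barzilai-Borwein gradient descent (O(pn) per iteration). Predictors are
#' standardized internally for conditioning and coefficients back-transformed.
#'
#' @param data Data frame, one row per individual.
#' @param phenotype Name of the response column.
#' @param predictors Character vector of predictor columns (an intercept is
#'   always added).
#' @param taus Strictly increasing quantile levels in (0, 1); default the
#'   estimation deciles.
#' @param bandwidth Smoothing bandwidth `h`, acting on the response after
#'   scaling it to unit standard deviation (the bandwidth rule is
#'   dimensionless); default [bandwidth_rule()].
#' @param tol Gradient sup-norm convergence tolerance; default
#'   `1e-5 * sd(y)`.
#' @param max_iter Maximum gradient iterations per quantile level.
#' @return A `quantile_fit` object: coefficient matrix (`taus` by terms),
#'   convergence flags, bandwidth, and the data needed for bootstrapping.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(x = rnorm(200), y = 1 + 2 * x + rnorm(200))
#' fit <- fit_quantile(d, "y", "x", taus = c(0.25, 0.5, 0.75))
#' tidy(fit)
#' @export
fit_quantile <- function(data, phenotype, predictors, taus = estimation_taus(),
                         bandwidth = NULL, tol = NULL, max_iter = 500L) {
  cols <- c(phenotype, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (anyNA(data[cols]))
    abort("`data` contains missing values in used columns; see read_dataset() for dropping rules.")
  y <- as.numeric(data[[phenotype]])
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  core <- smqr_core(y, X, taus, h = bandwidth, tol = tol, max_iter = max_iter)
  dimnames(core$coef) <- list(colnames(X), NULL)
  if (!all(core$converged))
    warn(sprintf("fit_quantile(): %d quantile level(s) did not converge in %d iterations.",
                 sum(!core$converged), max_iter))
  structure(
    list(taus = taus, coefficients = core$coef,
         terms = colnames(X), converged = as.logical(core$converged),
         iters = core$iters, bandwidth = core$h, tol = core$tol,
         n = length(y), p = ncol(X),
         phenotype = phenotype, predictors = predictors,
         y = y, X = X, core = core),
    class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Smoothed quantile regression: %s ~ %s\n", x$phenotype,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("n = %d, h = %.4f, %d quantile level(s)\n", x$n, x$bandwidth,
              length(x$taus)))
  print(round(t(x$coefficients), 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quantile_fit <- function(x, ...) {
  tibble(
    tau = rep(x$taus, each = x$p),
    term = rep(x$terms, times = length(x$taus)),
    estimate = as.vector(x$coefficients),
    converged = rep(x$converged, each = x$p)
  )
}

#' @exportS3Method generics::glance
glance.quantile_fit <- function(x, ...) {
  tibble(n = x$n, p = x$p, k_taus = length(x$taus), bandwidth = x$bandwidth,
         all_converged = all(x$converged))
}

#' Bootstrap covariance of one predictor's quantile coefficients
#'
#' Multiplier (weighted) bootstrap with exponential weights: each replicate
#' refits every quantile level under i.i.d. Exp(1) observation weights,
#' warm-started at the full-data solution, and the covariance of the focal
#' predictor's coefficients across quantile levels is returned.
#'
#' @param fit A [fit_quantile()] object.
#' @param focal Name (or index into the fit's terms) of the focal predictor.
#' @param B Number of bootstrap replicates (>= 2; >= 100 recommended).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return K x K symmetric positive semidefinite matrix (K = number of
#'   quantile levels), with the B x K replicate draws in attribute `"draws"`.
#' @export
bootstrap_cov <- function(fit, focal, B = 200L, seed = NULL) {
  stopifnot(inherits(fit, "quantile_fit"))
  if (B < 2) abort("bootstrap_cov() needs B >= 2 (>= 100 recommended).")
  j <- if (is.character(focal)) match(focal, fit$terms) else as.integer(focal)
  if (is.na(j) || j < 1 || j > fit$p) abort("`focal` does not name a fitted term.")
  W <- multiplier_weights(fit$n, B, seed)
  arr <- smqr_boot_core(fit$y, fit$core, fit$taus, W)
  draws <- t(arr[j, , , drop = TRUE])          # B x K
  if (length(fit$taus) == 1L) draws <- matrix(draws, ncol = 1L)
  S <- stats::cov(draws)
  S <- (S + t(S)) / 2
  attr(S, "draws") <- draws
  S
}
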