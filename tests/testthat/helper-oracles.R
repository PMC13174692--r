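# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact (unsmoothed) check-loss minimizer by vertex enumeration: some optimum
# of linear quantile regression interpolates p observations, so enumerating
# all non-singular p-subsets and scoring the raw check loss is exact.
# Feasible for n <= ~150, p <= 3.
exact_qr_oracle <- function(y, X, tau) {
  n <- length(y)
  p <- ncol(X)
  stopifnot(p <= 3, X[, 1] == 1)
  if (p == 1L) {
    cands <- matrix(unique(y), nrow = 1)
  } else if (p == 2L) {
    ij <- utils::combn(n, 2)
    x <- X[, 2]
    dx <- x[ij[1, ]] - x[ij[2, ]]
    ok <- abs(dx) > 1e-12
    slope <- (y[ij[1, ]] - y[ij[2, ]])[ok] / dx[ok]
    icpt <- y[ij[1, ]][ok] - slope * x[ij[1, ]][ok]
    cands <- rbind(icpt, slope)
  } else {
    # interpolate all observation triples; Cramer's rule, vectorized
    ijk <- utils::combn(n, 3)
    u <- X[, 2]; v <- X[, 3]
    u1 <- u[ijk[1, ]]; u2 <- u[ijk[2, ]]; u3 <- u[ijk[3, ]]
    v1 <- v[ijk[1, ]]; v2 <- v[ijk[2, ]]; v3 <- v[ijk[3, ]]
    y1 <- y[ijk[1, ]]; y2 <- y[ijk[2, ]]; y3 <- y[ijk[3, ]]
    det <- (u2 - u1) * (v3 - v1) - (u3 - u1) * (v2 - v1)
    ok <- abs(det) > 1e-10
    b2 <- ((y2 - y1) * (v3 - v1) - (y3 - y1) * (v2 - v1))[ok] / det[ok]
    b3 <- ((u2 - u1) * (y3 - y1) - (u3 - u1) * (y2 - y1))[ok] / det[ok]
    b1 <- y1[ok] - b2 * u1[ok] - b3 * v1[ok]
    cands <- rbind(b1, b2, b3)
  }
  best <- NULL
  best_loss <- Inf
  for (start in seq(1, ncol(cands), by = 2000)) {
    cols <- start:min(start + 1999, ncol(cands))
    U <- y - X %*% cands[, cols, drop = FALSE]
    l <- colSums(U * (tau - (U < 0)))
    j <- which.min(l)
    if (l[j] < best_loss) {
      best_loss <- l[j]
      best <- cands[, cols[j]]
    }
  }
  unname(best)
}

# Textbook A^2 formula for composite normality (mean/sd estimated), written
# directly from the order-statistic definition.
ad_stat_oracle <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  logp <- pnorm(z, log.p = TRUE)
  logq <- pnorm(rev(z), lower.tail = FALSE, log.p = TRUE)
  -n - mean((2 * seq_len(n) - 1) * (logp + logq))
}

# Smoothed check loss by adaptive quadrature of the convolution integral.
smoothed_loss_quad <- function(u, tau, h) {
  f <- function(v) (v * (tau - (v < 0))) * dnorm((v - u) / h) / h
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# one simulated dataset + design used by several suites
sim_fixture <- function(n = 1200, lambda0 = 0.5, seed = 42, ...) {
  sc <- sim_scenario(n = n, lambda0 = lambda0, ...)
  d <- simulate(sc, seed = seed)
  list(d = d, X = cbind(`(Intercept)` = 1, G = d$G,
                        as.matrix(d[grep("^C[0-9]+$", names(d))])))
}
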