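#' Box-Cox transformation
#'
#' Maps a strictly positive phenotype onto the candidate latent scale
#' \eqn{(y^\lambda - 1)/\lambda}, with the log transformation as the
#' \eqn{\lambda \to 0} limit. The map is strictly increasing in `y` for every
#' `lambda`, so quantile levels are comparable across scales.
#'
#' @param y Numeric vector of phenotype values on the default (observed) scale.
#' @param lambda Scale exponent \eqn{\lambda} (dimensionless). `|lambda| <
#'   1e-8` is treated as the log limit to avoid catastrophic cancellation.
#' @param positivity What to do when `y` contains non-positive values:
#'   `"error"` (default) rejects the input; `"shift"` adds
#'   `eps - min(y)` with `eps = 1e-6 * diff(range(y))` and records the shift in
#'   the `"shift"` attribute of the result.
#' @return Numeric vector on the `lambda` scale; carries a `"shift"` attribute
#'   when the shift policy fired.
#' @examples
#' box_cox(c(1, 4, 9), 0.5)
#' box_cox(exp(2), 0)  # log limit
#' @export
box_cox <- function(y, lambda, positivity = c("error", "shift")) {
  positivity <- match.arg(positivity)
  stopifnot(is.numeric(y), length(lambda) == 1L, is.finite(lambda))
  shift <- NULL
  if (any(y <= 0)) {
    n_bad <- sum(y <= 0)
    if (positivity == "error") {
      abort(sprintf(
        "box_cox() requires strictly positive input: %d value(s) <= 0. Use positivity = \"shift\" to offset.",
        n_bad))
    }
    shift <- 1e-6 * diff(range(y)) - min(y)
    y <- y + shift
    inform(sprintf("box_cox(): shifted %d non-positive value(s) by %.6g", n_bad, shift))
  }
  out <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  if (!is.null(shift)) attr(out, "shift") <- shift
  out
}

#' Inverse Box-Cox transformation
#'
#' Maps a latent-scale phenotype back to the default scale via
#' \eqn{y = (1 + \lambda y^*)^{1/\lambda}} (`exp(ystar)` in the log limit).
#' Exact inverse of [box_cox()]: `inv_box_cox(box_cox(y, l), l)` recovers `y`.
#'
#' @param ystar Numeric vector on the latent scale.
#' @inheritParams box_cox
#' @return Numeric vector on the default scale (strictly positive).
#' @export
inv_box_cox <- function(ystar, lambda) {
  stopifnot(is.numeric(ystar), length(lambda) == 1L, is.finite(lambda))
  if (abs(lambda) < 1e-8) return(exp(ystar))
  base <- 1 + lambda * ystar
  if (any(base <= 0)) {
    bad <- which(base <= 0)
    abort(sprintf(
      "inv_box_cox(): 1 + lambda*ystar <= 0 at %d index(es) (first few: %s); no real inverse exists there.",
      length(bad), paste(utils::head(bad, 5L), collapse = ", ")))
  }
  base^(1 / lambda)
}

#' Rank-based inverse normal transformation (RINT)
#'
#' Replaces values by standard-normal quantiles of their fractional ranks,
#' using the Blom offset `(rank - 3/8) / (n + 1/4)` conventional in GWAS.
#' Ties receive average ranks.
#'
#' @param y Numeric vector, length >= 2, not constant.
#' @return Numeric vector of normal scores; strictly monotone in the ranks.
#' @export
rint <- function(y) {
  stopifnot(is.numeric(y))
  if (length(y) < 2L) abort("rint() needs at least 2 observations.")
  if (diff(range(y)) == 0) abort("rint() is undefined for a constant vector.")
  r <- rank(y, ties.method = "average")
  qnorm((r - 3 / 8) / (length(y) + 1 / 4))
}

#' Anderson-Darling normality statistic
#'
#' The A-squared statistic for the composite null of normality with estimated
#' mean and standard deviation, used here as a residual diagnostic when
#' comparing phenotype scales. Larger values indicate stronger departure from
#' normality; the statistic is invariant to affine maps of the input.
#'
#' @param x Numeric vector of residuals, length >= 8, non-constant.
#' @return Single nonnegative number (the A-squared statistic).
#' @export
anderson_darling <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[is.finite(x)]
  if (length(x) < 8L) abort("anderson_darling() needs at least 8 finite observations.")
  if (sd(x) == 0) abort("anderson_darling() is undefined for zero-variance input.")
  unname(nortest::ad.test(x)$statistic)
}

#' Transform a phenotype column onto a chosen scale
#'
#' Data-frame-first wrapper around the scale maps: appends the transformed
#' phenotype as a new column and returns the tibble.
#'
#' @param data A data frame with one row per individual.
#' @param phenotype Name of the phenotype column (string).
#' @param scale One of `"boxcox"`, `"log"`, `"rint"`, `"default"`.
#' @param lambda Box-Cox exponent, required for `scale = "boxcox"`.
#' @param new_col Name for the transformed column; default
#'   `paste0(phenotype, "_", scale)`.
#' @inheritParams box_cox
#' @return `data` as a tibble with the transformed column appended.
#' @export
transform_phenotype <- function(data, phenotype, scale = c("boxcox", "log", "rint", "default"),
                                lambda = NULL, new_col = NULL,
                                positivity = c("error", "shift")) {
  scale <- match.arg(scale)
  positivity <- match.arg(positivity)
  if (!phenotype %in% names(data))
    abort(sprintf("Column '%s' not found in `data`.", phenotype))
  y <- data[[phenotype]]
  out <- apply_scale(y, scale, lambda, positivity = positivity)
  new_col <- new_col %||% paste0(phenotype, "_", scale)
  data <- as_tibble(data)
  data[[new_col]] <- as.numeric(out)
  data
}

# dispatch a scale tag to the corresponding map; `latent` passes through
# (simulation output is already on the latent scale)
apply_scale <- function(y, scale, lambda = NULL, positivity = "error") {
  switch(scale,
    default = ,
    latent  = y,
    log     = box_cox(y, 0, positivity = positivity),
    rint    = rint(y),
    boxcox  = {
      if (is.null(lambda)) abort("scale = \"boxcox\" requires `lambda`.")
      box_cox(y, lambda, positivity = positivity)
    },
    abort(sprintf("Unknown scale '%s'.", scale))
  )
}
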