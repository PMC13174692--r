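# ggplot2 autoplot methods for the main result types

#' Plot per-quantile coefficient profiles
#'
#' One line per term: coefficient estimate against quantile level. A flat
#' profile is the signature of an additive effect on the fitted scale.
#'
#' @param object A [fit_quantile()] object.
#' @param terms Terms to show (default all but the intercept).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.quantile_fit <- function(object, terms = NULL, ...) {
  td <- tidy(object)
  terms <- terms %||% setdiff(object$terms, "(Intercept)")
  td <- td[td$term %in% terms, , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$tau, y = .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "quantile level", y = "coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a heterogeneity-test effect profile
#'
#' The focal predictor's per-quantile effect with bootstrap error bars and
#' the constant-effect reference (the mean effect) as a dashed line.
#'
#' @param object A `het_result` from [quantile_het_scan()] or
#'   [wald_het_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.het_result <- function(object, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$tau, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = mean(object$betas), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "quantile level", y = "effect",
                  subtitle = sprintf("T = %.3g on %d df, p = %.3g%s",
                                     object$statistic, object$df, object$p_value,
                                     if (!is.na(object$scale_tag))
                                       paste0("  (", object$scale_tag, ")") else "")) +
    ggplot2::theme_minimal()
  if (!is.null(object$se) && all(is.finite(object$se)))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta - 1.96 * .data$se,
                   ymax = .data$beta + 1.96 * .data$se), width = 0.01)
  p
}

#' Plot the scale-estimation objective traces
#'
#' Per-covariate Wald-objective curves over candidate `lambda`, with the
#' pooled estimate and its confidence interval marked.
#'
#' @param object A [estimate_scale()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scale_estimate <- function(object, ...) {
  tr <- dplyr::bind_rows(object$objective_trace)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$lambda, y = .data$objective,
                                   colour = .data$covariate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda_hat) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda), y = "Wald objective (log scale)",
                  colour = NULL,
                  subtitle = sprintf("lambda0 = %.3f [%.3f, %.3f]",
                                     object$lambda_hat, object$ci_low,
                                     object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot the Gaussian-likelihood trace of a warped fit
#'
#' @param object A [fit_warped()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.warped_fit <- function(object, ...) {
  ggplot2::ggplot(object$loglik_trace,
                  ggplot2::aes(x = .data$lambda, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(xintercept = object$lambda_hat, linetype = "dashed") +
    ggplot2::labs(x = expression(lambda), y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}
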