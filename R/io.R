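#' Read and validate a phenotype/covariate/predictor table
#'
#' Reads a delimited text file (tab or comma, auto-detected from the header
#' line unless `delimiter` is given), checks that the named columns exist and
#' are numeric, drops rows with missing values in used columns (counted), and
#' optionally drops phenotype outliers beyond `outlier_sd` standard
#' deviations of the mean.
#'
#' @param path Path to a delimited text file with a header row.
#' @param phenotype Phenotype column name.
#' @param covariates,predictors Optional character vectors of column names.
#' @param id Optional ID column; row index is used when absent. IDs must be
#'   unique.
#' @param delimiter `"\t"` or `","`; `NULL` (default) auto-detects.
#' @param outlier_sd Drop rows whose phenotype is more than this many SDs
#'   from the mean; `NULL` (default) disables the filter (6 is the
#'   conventional robustness choice).
#' @param quiet Suppress the ingestion summary message.
#' @return A tibble with columns `id`, the phenotype, covariates and
#'   predictors; attributes `n_read`, `n_dropped_na`, `n_dropped_outlier`.
#' @export
read_dataset <- function(path, phenotype, covariates = NULL, predictors = NULL,
                         id = NULL, delimiter = NULL, outlier_sd = NULL,
                         quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  used <- c(phenotype, covariates, predictors)
  missing_cols <- setdiff(c(used, id), names(raw))
  if (length(missing_cols))
    abort(paste0("Column(s) not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  for (cl in used) {
    if (!is.numeric(raw[[cl]])) {
      coerced <- suppressWarnings(as.numeric(raw[[cl]]))
      n_bad <- sum(is.na(coerced) & !is.na(raw[[cl]]) & raw[[cl]] != "")
      if (n_bad > 0)
        abort(sprintf("Column '%s' has %d non-numeric cell(s).", cl, n_bad))
      raw[[cl]] <- coerced
    }
  }
  n_read <- nrow(raw)
  ok <- complete.cases(raw[used])
  n_dropped_na <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  n_dropped_outlier <- 0L
  if (!is.null(outlier_sd)) {
    y <- raw[[phenotype]]
    keep <- abs(y - mean(y)) <= outlier_sd * sd(y)
    n_dropped_outlier <- sum(!keep)
    raw <- raw[keep, , drop = FALSE]
  }
  if (nrow(raw) == 0) abort("No rows remain after dropping incomplete records.")
  ids <- if (is.null(id)) seq_len(nrow(raw)) else raw[[id]]
  if (anyDuplicated(ids)) abort("ID column contains duplicates.")
  out <- dplyr::bind_cols(tibble(id = ids), as_tibble(raw[used]))
  attr(out, "n_read") <- n_read
  attr(out, "n_dropped_na") <- n_dropped_na
  attr(out, "n_dropped_outlier") <- n_dropped_outlier
  if (!quiet)
    inform(sprintf("read_dataset(): %d rows read, %d dropped (missing), %d dropped (outlier), %d kept.",
                   n_read, n_dropped_na, n_dropped_outlier, nrow(out)))
  out
}

format6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- format6(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

sidecar <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("siqreg"))
  jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

#' Write a result object to TSV with a JSON provenance sidecar
#'
#' Writes a fixed-schema TSV (floats at 6 significant digits) and a
#' `<path>.json` sidecar holding the full configuration, seed, and package
#' version, so the run can be reproduced byte-identically.
#'
#' @param x A `scale_estimate`, `het_result`, `warped_fit`, or data frame.
#' @param path Output TSV path.
#' @param config Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = list()) UseMethod("write_results")

#' @export
write_results.scale_estimate <- function(x, path, config = list()) {
  summary_row <- tibble(covariate = "(meta)", lambda_hat = x$lambda_hat,
                        se = x$se, objective = NA_real_,
                        uninformative = FALSE, boundary = FALSE)
  write_tsv_plain(dplyr::bind_rows(summary_row, x$per_covariate), path)
  sidecar(path, c(list(
    type = "scale_estimate", phenotype = x$phenotype, covariates = x$covariates,
    taus = x$taus, bootstrap = x$B, subsamples = x$R, seed = x$seed,
    interval = x$interval, n = x$n, lambda_hat = x$lambda_hat, se = x$se,
    ci = c(x$ci_low, x$ci_high),
    objective_trace = lapply(x$objective_trace, as.list)), config))
  invisible(path)
}

#' @export
write_results.het_result <- function(x, path, config = list()) {
  taus <- x$taus %||% seq_along(x$betas)
  rows <- tibble(row = "tau", tau = taus, estimate = x$betas,
                 se = x$se %||% rep(NA_real_, length(x$betas)))
  test_row <- tibble(row = "test", tau = NA_real_, estimate = x$statistic,
                     se = NA_real_)
  test_row$df <- x$df
  test_row$p_value <- x$p_value
  rows$df <- NA_integer_
  rows$p_value <- NA_real_
  write_tsv_plain(dplyr::bind_rows(rows, test_row), path)
  sidecar(path, c(list(type = "het_result", scale = x$scale_tag,
                       statistic = x$statistic, df = x$df,
                       p_value = x$p_value), config))
  invisible(path)
}

#' @export
write_results.warped_fit <- function(x, path, config = list()) {
  write_tsv_plain(tibble(term = c("lambda_hat", names(x$coefficients),
                                  "residual_variance"),
                         estimate = c(x$lambda_hat, unname(x$coefficients),
                                      x$residual_variance)), path)
  sidecar(path, c(list(type = "warped_fit", phenotype = x$phenotype,
                       covariates = x$covariates, lambda_hat = x$lambda_hat,
                       boundary = x$boundary), config))
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, config = list()) {
  write_tsv_plain(x, path)
  sidecar(path, c(list(type = "table"), config))
  invisible(path)
}
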