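#' Fit a univariate linear QSPR model
#'
#' Fits the model \eqn{P = A + B \cdot TI} by ordinary least squares, where
#' `P` is a physicochemical property and `TI` a topological index, and
#' computes the full set of inference statistics: signed and absolute Pearson
#' correlation, \eqn{r^2}, the F statistic \eqn{r^2 (n-2)/(1-r^2)} with
#' (1, n-2) degrees of freedom, its upper-tail p-value, the standard error of
#' the estimate \eqn{\sqrt{SS_{res}/(n-2)}}, and a significance flag at
#' p < 0.05.
#'
#' A perfect fit (\eqn{r^2 = 1}) leaves the F statistic undefined; it is
#' reported as `Inf` with `p_value = 0` and `boundary = TRUE` so pipelines
#' stay total.
#'
#' @param data A data frame holding one row per compound, containing the
#'   columns named by `property` and `index` (e.g. the join of
#'   [compute_indices()] output with compound properties).
#' @param property Name of the response column, e.g. `"melting_point"`.
#' @param index Name of the predictor column, e.g. `"F"`.
#' @return An object of class `qspr_fit`. Use [tidy()][generics::tidy],
#'   [glance()][generics::glance], [predict()][predict.qspr_fit] and
#'   [autoplot()][autoplot.qspr_fit] to work with it.
#' @examples
#' d <- dplyr::left_join(compute_indices(sulfonamide_compounds()),
#'                       sulfonamide_compounds()[c("compound", "melting_point")],
#'                       by = "compound")
#' fit_qspr(d, "melting_point", "F")
#' @export
fit_qspr <- function(data, property, index) {
  stopifnot(is.data.frame(data))
  for (col in c(property, index)) {
    if (!col %in% names(data)) {
      rlang::abort(sprintf("Column '%s' not found in `data`.", col),
                   class = "tiqspr_error_schema")
    }
  }
  x <- as.numeric(data[[index]])
  y <- as.numeric(data[[property]])
  n <- length(x)
  if (n < 3) {
    rlang::abort(
      sprintf("Regression of %s on %s needs at least 3 compounds (got %d).",
              property, index, n),
      class = "tiqspr_error_insufficient_data"
    )
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    rlang::abort("Predictor and response must be finite.", class = "tiqspr_error_schema")
  }

  x_mean <- mean(x)
  y_mean <- mean(y)
  sxx <- sum((x - x_mean)^2)
  syy <- sum((y - y_mean)^2)
  sxy <- sum((x - x_mean) * (y - y_mean))
  if (sxx == 0) {
    rlang::abort(sprintf("Predictor '%s' is constant.", index),
                 class = "tiqspr_error_degenerate_predictor")
  }
  if (syy == 0) {
    rlang::abort(sprintf("Response '%s' is constant.", property),
                 class = "tiqspr_error_degenerate_response")
  }

  B <- sxy / sxx
  A <- y_mean - B * x_mean
  r <- sxy / sqrt(sxx * syy)
  r2 <- r^2
  ss_res <- max(syy - B * sxy, 0)
  boundary <- (1 - r2) < 1e-12
  f_stat <- if (boundary) Inf else r2 * (n - 2) / (1 - r2)
  p_value <- if (boundary) 0 else f_upper_tail(f_stat, 1, n - 2)
  fitted <- A + B * x

  structure(
    list(
      property = property, index = index, n = n,
      A = A, B = B,
      r = r, r_abs = abs(r), r2 = r2,
      f_stat = f_stat, p_value = p_value,
      se_estimate = sqrt(ss_res / (n - 2)),
      significant = p_value < 0.05,
      boundary = boundary,
      x = x, y = y, x_mean = x_mean, y_mean = y_mean,
      sxx = sxx, fitted = fitted, residuals = y - fitted
    ),
    class = "qspr_fit"
  )
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf("<qspr_fit>  %s = %.6g %s %.6g * %s\n",
              x$property, x$A, ifelse(x$B < 0, "-", "+"), abs(x$B), x$index))
  cat(sprintf("  n = %d  |r| = %.4f  r2 = %.4f  F(1,%d) = %.4g  p = %.4g  SE = %.4f  [%s]\n",
              x$n, x$r_abs, x$r2, x$n - 2, x$f_stat, x$p_value, x$se_estimate,
              ifelse(x$significant, "Significant", "Non-Significant")))
  invisible(x)
}

#' Tidy a QSPR fit
#'
#' @param x A `qspr_fit`.
#' @param ... Unused.
#' @return A two-row tibble (intercept, slope) with columns `term`,
#'   `estimate`, `std.error`, `statistic` (t), `p.value`. The squared slope t
#'   statistic equals the model F statistic.
#' @method tidy qspr_fit
#' @export
tidy.qspr_fit <- function(x, ...) {
  se_b <- x$se_estimate / sqrt(x$sxx)
  se_a <- x$se_estimate * sqrt(1 / x$n + x$x_mean^2 / x$sxx)
  est <- c(x$A, x$B)
  se <- c(se_a, se_b)
  tstat <- ifelse(se > 0, est / se, sign(est) * Inf)
  tibble::tibble(
    term = c("(Intercept)", x$index),
    estimate = est,
    std.error = se,
    statistic = tstat,
    p.value = 2 * stats::pt(abs(tstat), df = x$n - 2, lower.tail = FALSE)
  )
}

#' Glance at a QSPR fit
#'
#' @param x A `qspr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `r` (signed), `r.abs`, `r.squared`,
#'   `statistic` (F), `p.value`, `sigma` (standard error of the estimate),
#'   `df.residual`, `nobs`, `significant`.
#' @method glance qspr_fit
#' @export
glance.qspr_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, r.abs = x$r_abs, r.squared = x$r2,
    statistic = x$f_stat, p.value = x$p_value, sigma = x$se_estimate,
    df.residual = x$n - 2, nobs = x$n, significant = x$significant
  )
}

#' Predict from a QSPR fit
#'
#' @param object A `qspr_fit`.
#' @param newdata A numeric vector of index values, or a data frame containing
#'   the fit's index column. `NULL` returns fitted values.
#' @param ... Unused.
#' @return Numeric vector of `A + B * x`.
#' @export
predict.qspr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x0 <- if (is.data.frame(newdata)) {
    if (!object$index %in% names(newdata)) {
      rlang::abort(sprintf("`newdata` lacks column '%s'.", object$index),
                   class = "tiqspr_error_schema")
    }
    as.numeric(newdata[[object$index]])
  } else {
    as.numeric(newdata)
  }
  object$A + object$B * x0
}

#' Upper tail of the F distribution
#'
#' The reference distribution of the regression F statistic with
#' `(df1, df2)` degrees of freedom: returns \eqn{P(F > f)}, strictly
#' decreasing in `f`, with value 1 at `f = 0`.
#'
#' @param f Non-negative finite F statistic (vectorised).
#' @param df1,df2 Positive integer degrees of freedom.
#' @return Probabilities in `(0, 1]`.
#' @export
f_upper_tail <- function(f, df1, df2) {
  if (any(!is.finite(f)) || any(f < 0)) {
    rlang::abort("`f` must be finite and non-negative.", class = "tiqspr_error_domain")
  }
  for (d in list(df1, df2)) {
    if (length(d) != 1 || !is.finite(d) || d < 1 || d != round(d)) {
      rlang::abort("Degrees of freedom must be positive integers.",
                   class = "tiqspr_error_domain")
    }
  }
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Fit all property-by-index QSPR models
#'
#' Fits one univariate model per (property, index) pair and collects the
#' statistics reported in QSPR tables: intercept, slope, absolute correlation,
#' \eqn{r^2}, F, p, standard error of the estimate and the significance call.
#'
#' @param data A data frame with one row per compound containing all property
#'   and index columns (see [fit_qspr()]).
#' @param properties Character vector of response column names.
#' @param indices Character vector of predictor column names.
#' @return A tibble with one row per model: columns `property`, `index`, `n`,
#'   `A`, `B`, `r_abs`, `r2`, `f_stat`, `p_value`, `se_estimate`,
#'   `significant`, and a list-column `fit` of `qspr_fit` objects. The slope
#'   keeps its sign; correlations are reported as absolute values.
#' @export
fit_qspr_models <- function(data,
                            properties = c("melting_point", "formula_weight"),
                            indices = intersect(index_ids(), names(data))) {
  grid <- tidyr::expand_grid(property = properties, index = indices)
  fits <- purrr::map2(grid$property, grid$index, ~ fit_qspr(data, .x, .y))
  dplyr::bind_cols(
    grid,
    purrr::map_dfr(fits, function(f) {
      tibble::tibble(n = f$n, A = f$A, B = f$B, r_abs = f$r_abs, r2 = f$r2,
                     f_stat = f$f_stat, p_value = f$p_value,
                     se_estimate = f$se_estimate, significant = f$significant)
    }),
    tibble::tibble(fit = fits)
  )
}

#' Absolute correlation of each index with each property
#'
#' @inheritParams fit_qspr_models
#' @return A tibble with column `index` and one column per property holding
#'   the absolute Pearson correlation in `[0, 1]`. A constant predictor or
#'   response yields `NA` for the affected cells, with a warning, rather than
#'   a global failure.
#' @examples
#' cmp <- sulfonamide_compounds()
#' correlation_table(dplyr::left_join(compute_indices(cmp),
#'                   cmp[c("compound", "melting_point", "formula_weight")],
#'                   by = "compound"))
#' @export
correlation_table <- function(data,
                              properties = c("melting_point", "formula_weight"),
                              indices = intersect(index_ids(), names(data))) {
  if (nrow(data) < 3) {
    rlang::abort("Correlation table needs at least 3 compounds.",
                 class = "tiqspr_error_insufficient_data")
  }
  long <- tidyr::expand_grid(index = indices, property = properties)
  long$r_abs <- purrr::map2_dbl(long$index, long$property, function(ix, pp) {
    x <- as.numeric(data[[ix]])
    y <- as.numeric(data[[pp]])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    abs(stats::cor(x, y))
  })
  if (anyNA(long$r_abs)) {
    bad <- long[is.na(long$r_abs), ]
    rlang::warn(sprintf(
      "Degenerate (constant) column for %s; correlation set to NA.",
      paste(sprintf("%s ~ %s", bad$property, bad$index), collapse = ", ")
    ))
  }
  tidyr::pivot_wider(long, names_from = "property", values_from = "r_abs") |>
    dplyr::relocate("index")
}

#' Standard errors of the estimate, by index and property
#'
#' @param models Output of [fit_qspr_models()].
#' @return A tibble with column `index` and one column per property holding
#'   \eqn{\sqrt{SS_{res}/(n-2)}}.
#' @export
standard_error_table <- function(models) {
  models |>
    dplyr::select("property", "index", "se_estimate") |>
    tidyr::pivot_wider(names_from = "property", values_from = "se_estimate")
}

#' Actual-versus-predicted table for one property
#'
#' One row per compound: the observed property value followed by the value
#' predicted from each index's univariate model. Values are kept at full
#' precision; round only for display.
#'
#' @param models Output of [fit_qspr_models()].
#' @param data The compound-by-descriptor data the models were fit on
#'   (must contain `compound`, the property column and all index columns).
#' @param property The property to tabulate.
#' @return A tibble with columns `compound`, `actual`, then one column per
#'   index.
#' @export
prediction_table <- function(models, data, property) {
  rows <- dplyr::filter(models, .data$property == !!property)
  if (nrow(rows) == 0) {
    rlang::abort(sprintf("No fitted models for property '%s'.", property),
                 class = "tiqspr_error_schema")
  }
  preds <- purrr::map(rows$fit, ~ predict(.x, data))
  names(preds) <- rows$index
  dplyr::bind_cols(
    tibble::tibble(compound = data$compound, actual = as.numeric(data[[property]])),
    tibble::as_tibble(preds)
  )
}
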