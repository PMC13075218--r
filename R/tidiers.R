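# broom-style tidiers for the package's result objects.

#' Tidy a cross-validation result
#'
#' @param x A `canopyn_cv` from [loocv()].
#' @param ... Unused.
#' @return The held-out predictions: tree_id, y, y_hat, fold.
#' @export
tidy.canopyn_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation result
#'
#' @param x A `canopyn_cv` from [loocv()].
#' @param ... Unused.
#' @return A one-row tibble with the model family, pooled metrics and the
#'   repeat spread.
#' @export
glance.canopyn_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$spec$family),
    x$metrics,
    tibble::tibble(
      r2_sd = if (is.null(x$spread)) 0 else x$spread$r2,
      rmse_sd = if (is.null(x$spread)) 0 else x$spread$rmse,
      repeats = x$repeats,
      n_failed_folds = length(x$failed_folds)
    )
  )
}

#' Tidy a one-way ANOVA
#'
#' @param x A `canopyn_anova`.
#' @param ... Unused.
#' @return A tibble with one row per group mean.
#' @export
tidy.canopyn_anova <- function(x, ...) {
  tibble::tibble(
    group = names(x$group_means) %||% paste0("g", seq_along(x$group_means)),
    mean = as.numeric(x$group_means),
    n = x$group_ns
  )
}

#' One-row summary of a one-way ANOVA
#'
#' @param x A `canopyn_anova`.
#' @param ... Unused.
#' @return A one-row tibble: statistic, df, p.value, sums of squares.
#' @export
glance.canopyn_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f, df = x$df_between, df.residual = x$df_within,
    p.value = x$p_value, ss_between = x$ss_between, ss_within = x$ss_within
  )
}

#' Tidy a band-pair score matrix
#'
#' @param x A `canopyn_score_matrix`.
#' @param ... Unused.
#' @return A long tibble: lambda_i, lambda_j, score (upper triangle only).
#' @export
tidy.canopyn_score_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$scores), arr.ind = TRUE)
  tibble::tibble(
    lambda_i = x$wavelengths[idx[, 1]],
    lambda_j = x$wavelengths[idx[, 2]],
    score = x$scores[idx]
  )
}
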