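# ggplot2 visualisations for the main result types.

#' Plot a band-pair score map
#'
#' The classic full-spectrum contour map: score of the NDSI at every
#' (lambda_i, lambda_j) pair against the trait.
#'
#' @param object A `canopyn_score_matrix` from [band_pair_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.canopyn_score_matrix <- function(object, ...) {
  df <- tidy(object)
  best <- select_best_pair(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda_i, .data$lambda_j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_point(
      data = best, ggplot2::aes(.data$lambda_i, .data$lambda_j),
      shape = 4, size = 2, colour = "white"
    ) +
    ggplot2::scale_fill_viridis_c(name = expression(R^2), limits = c(0, 1)) +
    ggplot2::labs(
      x = expression(lambda[i] ~ "(nm)"), y = expression(lambda[j] ~ "(nm)"),
      title = sprintf(
        "NDSI band-pair screen: best (%d, %d), score %.2f",
        best$lambda_i_nm, best$lambda_j_nm, best$score
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs LOOCV-predicted values
#'
#' @param object A `canopyn_cv` from [loocv()].
#' @param ... Unused.
#' @return A ggplot with the 1:1 line.
#' @export
autoplot.canopyn_cv <- function(object, ...) {
  df <- object$predictions
  m <- object$metrics
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$y_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Observed", y = "LOOCV predicted",
      title = sprintf(
        "%s: R2 = %.2f, RMSE = %.2f (n = %d)",
        object$spec$family, m$r2, m$rmse, m$n
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot spectra
#'
#' @param spectra A wide spectra tibble.
#' @param colour_by Optional metadata column name to colour lines by.
#' @return A ggplot of reflectance against wavelength.
#' @export
plot_spectra <- function(spectra, colour_by = NULL) {
  long <- spectra_longer(spectra)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
    group = .data$sample_id
  ))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(colour = factor(.data[[colour_by]])),
      alpha = 0.6
    ) + ggplot2::labs(colour = colour_by)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.4)
  }
  p + ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance") +
    ggplot2::theme_minimal()
}
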