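#' The hyperspectral wavelength grid
#'
#' The imaging spectrometer samples 561 channels from 400 nm at a 1.07 nm
#' interval, so band `k` (1-based) sits at `400 + 1.07 * (k - 1)` nm and the
#' last band at 999.2 nm. All spectra handled by the package live on this grid.
#'
#' @param start First wavelength in nm.
#' @param step Sampling interval in nm.
#' @param n_bands Number of spectral channels.
#'
#' @return A numeric vector of wavelengths (nm) of length `n_bands`.
#' @export
#'
#' @examples
#' wl <- wavelength_grid()
#' range(wl)
wavelength_grid <- function(start = 400, step = 1.07, n_bands = 561) {
  assert_scalar_number(start, "start", lower = 0)
  assert_scalar_number(step, "step", lower = 0, strict_lower = TRUE)
  start + step * (seq_len(n_bands) - 1)
}

#' Map wavelengths to the nearest grid band
#'
#' @param lambda Wavelengths in nm.
#' @param grid Wavelength grid (defaults to [wavelength_grid()]).
#'
#' @return Integer band indices into `grid`.
#' @export
band_index <- function(lambda, grid = wavelength_grid()) {
  if (!is.numeric(lambda) || any(!is.finite(lambda))) {
    stop_input("`lambda` must be finite wavelengths in nm.")
  }
  lo <- min(grid) - 1e-9
  hi <- max(grid) + 1e-9
  if (any(lambda < lo | lambda > hi)) {
    stop_input(sprintf(
      "wavelength outside the %.1f-%.1f nm grid: %s",
      min(grid), max(grid), paste(lambda[lambda < lo | lambda > hi], collapse = ", ")
    ))
  }
  vapply(lambda, function(l) which.min(abs(grid - l)), integer(1))
}

band_names <- function(grid = wavelength_grid()) sprintf("%.2f", grid)

# Columns of a wide spectra tibble that are reflectance bands.
spectra_band_cols <- function(spectra) {
  nm <- names(spectra)
  nm[grepl("^[0-9]+\\.[0-9]{2}$", nm)]
}

#' Extract the reflectance matrix from a wide spectra table
#'
#' Wide spectra tables carry one row per sample with metadata columns
#' (`sample_id`, `site`, `stage`, `altitude`, ...) followed by one column per
#' band, named by wavelength to two decimals (e.g. `"400.00"`).
#'
#' @param spectra A wide spectra tibble.
#'
#' @return A numeric matrix (samples x bands) with wavelength column names and
#'   `sample_id` row names.
#' @export
reflectance_matrix <- function(spectra) {
  cols <- spectra_band_cols(spectra)
  if (length(cols) == 0) stop_input("no reflectance band columns found.")
  m <- as.matrix(spectra[, cols])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(spectra)) rownames(m) <- spectra$sample_id
  m
}

#' Wavelengths of a wide spectra table
#'
#' @param spectra A wide spectra tibble.
#' @return Numeric wavelengths (nm) for the band columns.
#' @export
spectra_wavelengths <- function(spectra) {
  as.numeric(spectra_band_cols(spectra))
}

#' Pivot spectra between wide and long layouts
#'
#' @param spectra A wide spectra tibble.
#' @return `spectra_longer()`: a long tibble with `wavelength` and
#'   `reflectance` columns; `spectra_wider()` inverts it.
#' @export
spectra_longer <- function(spectra) {
  tidyr::pivot_longer(spectra,
    cols = dplyr::all_of(spectra_band_cols(spectra)),
    names_to = "wavelength", values_to = "reflectance",
    names_transform = list(wavelength = as.numeric)
  )
}

#' @rdname spectra_longer
#' @param long A long spectra tibble from [spectra_longer()].
#' @export
spectra_wider <- function(long) {
  tidyr::pivot_wider(long,
    names_from = "wavelength", values_from = "reflectance",
    names_glue = "{sprintf('%.2f', wavelength)}"
  )
}
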