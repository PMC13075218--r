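#' Acquisition-scene parameters for one flight altitude
#'
#' Captures how flight altitude degrades the canopy signal: a larger ground
#' footprint mixes more bare-soil reflectance into each canopy pixel and adds
#' more sensor noise. Defaults follow the package's altitude ladder: soil
#' fractions 0.05/0.10/0.15 and noise SDs 0.005/0.008/0.012 at 60/80/100 m,
#' chosen to make altitude effects detectable but not dominant.
#'
#' @param altitude Flight altitude in m; one of `allowed`.
#' @param soil_fraction Fraction of soil signal mixed into the pixel, in
#'   `[0, 1)`. Defaults to the altitude ladder.
#' @param noise_sd Additive Gaussian noise SD in reflectance units.
#' @param soil_reflectance Soil reflectance on the wavelength grid, or `NULL`
#'   for the built-in brightening-with-wavelength soil curve.
#' @param allowed Permitted altitudes (validated, not hard-coded).
#' @param grid Wavelength grid.
#'
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(altitude = 60,
                         soil_fraction = NULL,
                         noise_sd = NULL,
                         soil_reflectance = NULL,
                         allowed = c(60, 80, 100),
                         grid = wavelength_grid()) {
  if (!altitude %in% allowed) {
    stop_input(sprintf(
      "altitude %s not allowed; must be one of {%s}.",
      altitude, paste(allowed, collapse = ", ")
    ))
  }
  ladder <- data.frame(
    altitude = c(60, 80, 100),
    soil_fraction = c(0.05, 0.10, 0.15),
    noise_sd = c(0.005, 0.008, 0.012)
  )
  row <- ladder[match(altitude, ladder$altitude), ]
  if (is.null(soil_fraction)) soil_fraction <- row$soil_fraction
  if (is.null(noise_sd)) noise_sd <- row$noise_sd
  assert_scalar_number(soil_fraction, "soil_fraction", lower = 0, upper = 0.999)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(soil_reflectance)) soil_reflectance <- soil_spectrum(grid)
  if (length(soil_reflectance) != length(grid)) {
    stop_input("`soil_reflectance` must match the wavelength grid length.")
  }
  structure(
    list(
      altitude = altitude, soil_fraction = soil_fraction,
      noise_sd = noise_sd, soil_reflectance = soil_reflectance, grid = grid
    ),
    class = "scene_params"
  )
}

#' Default scene set for the three flight altitudes
#'
#' @param altitudes Altitudes to include.
#' @return A named list of [scene_params()], keyed by altitude.
#' @export
default_scenes <- function(altitudes = c(60, 80, 100)) {
  stats::setNames(
    lapply(altitudes, scene_params),
    as.character(altitudes)
  )
}

#' Built-in soil reflectance curve
#'
#' A bare purple-soil surrogate: brighter than green vegetation through the
#' visible, dimmer than a dense canopy's NIR plateau, rising gently with
#' wavelength.
#'
#' @param grid Wavelength grid (nm).
#' @return Reflectance values in `[0, 1]`.
#' @export
soil_spectrum <- function(grid = wavelength_grid()) {
  0.14 + 0.22 * (grid - 400) / 600
}

# Deterministic canopy reflectance model: pigment absorption wells at ~450 and
# ~670 nm whose depth grows (and saturates) with nitrogen-linked chlorophyll,
# a green reflectance peak near 550 nm, and a logistic red edge near 715 nm
# rising to a NIR plateau that scales with canopy density.
canopy_reflectance <- function(cnc, canopy_density, grid = wavelength_grid()) {
  assert_scalar_number(cnc, "cnc", lower = 0, strict_lower = TRUE)
  assert_scalar_number(canopy_density, "canopy_density",
    lower = 0, upper = 1, strict_lower = TRUE
  )
  s <- stats::plogis((grid - 715) / 12)
  vis <- 0.12 + 0.05 * exp(-(grid - 550)^2 / (2 * 28^2))
  # Chlorophyll absorption depth saturates in nitrogen: dense perennial
  # canopies lose index sensitivity at high chlorophyll, so the depth-CNC
  # curve is steep at low CNC and flattens towards the top of the range.
  depth <- pmax(0, 2.2 - 11 * exp(-0.09 * cnc))
  absorb <- depth * (
    0.7 * exp(-(grid - 450)^2 / (2 * 32^2)) + exp(-(grid - 670)^2 / (2 * 26^2))
  )
  # NIR plateau saturates in canopy density (the optical "saturation effect"
  # that blinds passive sensors to canopy volume once foliage is dense).
  plateau <- 0.18 + 0.38 * (1 - exp(-3 * canopy_density)) / (1 - exp(-3))
  vis * exp(-absorb) * (1 - s) + plateau * s
}

#' Simulate one canopy reflectance spectrum
#'
#' Mixes the deterministic canopy model with the scene's soil spectrum
#' (`(1 - f) * canopy + f * soil`), adds band-wise Gaussian noise and clips to
#' `[0, 1]`. With `noise_sd = 0` the output is fully deterministic.
#'
#' @param cnc Canopy nitrogen concentration in g kg-1 (> 0).
#' @param canopy_density Dimensionless canopy density / LAI proxy in `(0, 1]`;
#'   controls the NIR plateau height.
#' @param scene A [scene_params()] object.
#' @param seed Integer seed for the noise draw.
#'
#' @return A long tibble with columns `wavelength` (nm) and `reflectance`,
#'   with the scene altitude attached as attribute `"altitude"`.
#' @export
#'
#' @examples
#' sp <- generate_canopy_spectrum(35, 0.7, scene_params(60), seed = 1)
#' head(sp)
generate_canopy_spectrum <- function(cnc, canopy_density,
                                     scene = scene_params(60), seed = 1) {
  if (!inherits(scene, "scene_params")) {
    stop_input("`scene` must come from scene_params().")
  }
  refl <- spectrum_vector(cnc, canopy_density, scene,
    seed = derive_seed(seed, "spectrum")
  )
  out <- tibble::tibble(wavelength = scene$grid, reflectance = refl)
  attr(out, "altitude") <- scene$altitude
  out
}

spectrum_vector <- function(cnc, canopy_density, scene, seed) {
  canopy <- canopy_reflectance(cnc, canopy_density, scene$grid)
  mix <- (1 - scene$soil_fraction) * canopy +
    scene$soil_fraction * scene$soil_reflectance
  if (scene$noise_sd > 0) {
    mix <- mix + with_seed(seed, rnorm(length(mix), 0, scene$noise_sd))
  }
  pmin(pmax(mix, 0), 1)
}

#' Simulate spectra with sensitivity planted at a known band pair
#'
#' Builds `n` spectra around a fixed canopy baseline, adds smooth nuisance
#' variation (independent plateau and visible-brightness shifts), band noise,
#' and a trait-linked antisymmetric perturbation: a narrow Gaussian bump at
#' `lambda_a` minus the same bump at `lambda_b`, scaled by each sample's
#' trait value. A full-spectrum NDSI screen should therefore recover the
#' planted pair.
#'
#' @param n Number of samples.
#' @param lambda_a,lambda_b Planted wavelengths (nm).
#' @param beta Amplitude of the planted perturbation.
#' @param bump_sd Width (nm) of the planted Gaussian bump.
#' @param noise_sd Band-wise Gaussian noise SD.
#' @param seed Integer seed.
#'
#' @return A list with `spectra` (wide tibble, one row per sample) and
#'   `trait` (numeric vector of length `n`).
#' @export
simulate_planted_pair <- function(n, lambda_a, lambda_b, beta = 0.06,
                                  bump_sd = 3, noise_sd = 0.004, seed = 1) {
  assert_scalar_number(n, "n", lower = 4)
  grid <- wavelength_grid()
  band_index(c(lambda_a, lambda_b)) # validates range
  base <- canopy_reflectance(30, 0.7, grid)
  s <- stats::plogis((grid - 715) / 12)
  visshape <- 1 - s
  bump_a <- exp(-(grid - lambda_a)^2 / (2 * bump_sd^2))
  bump_b <- exp(-(grid - lambda_b)^2 / (2 * bump_sd^2))
  dat <- with_seed(derive_seed(seed, "planted"), {
    trait <- runif(n)
    u <- rnorm(n, 0, 1)
    v <- rnorm(n, 0, 1)
    noise <- matrix(rnorm(n * length(grid), 0, noise_sd), n)
    list(trait = trait, u = u, v = v, noise = noise)
  })
  m <- matrix(rep(base, each = n), n) +
    outer(dat$u * 0.02, s) + outer(dat$v * 0.01, visshape) +
    outer(beta * (dat$trait - 0.5), bump_a - bump_b) + dat$noise
  m <- pmin(pmax(m, 0), 1)
  colnames(m) <- band_names(grid)
  spectra <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(n))),
    tibble::as_tibble(m)
  )
  list(spectra = spectra, trait = dat$trait)
}
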