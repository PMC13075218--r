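# Shared fixtures, generated in code.

# A tiny wide spectra tibble on an arbitrary band subset: n samples x bands.
toy_spectra <- function(m, wavelengths) {
  colnames(m) <- sprintf("%.2f", wavelengths)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  )
}

# Uniform points inside an axis-aligned ellipsoid (a, a, c semi-axes).
ellipsoid_points <- function(n, a, c_ax, centre = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- stats::runif(n)^(1 / 3)
  cbind(
    centre[1] + a * r * u[, 1],
    centre[2] + a * r * u[, 2],
    centre[3] + c_ax * r * u[, 3]
  )
}

# Brute-force NDSI band-pair R2 screen (independent oracle).
brute_force_screen <- function(spectra, trait) {
  m <- canopyn::reflectance_matrix(spectra)
  b <- ncol(m)
  out <- matrix(0, b, b)
  for (i in seq_len(b - 1)) {
    for (j in (i + 1):b) {
      nd <- (m[, i] - m[, j]) / (m[, i] + m[, j])
      nd[!is.finite(nd)] <- NA
      r <- suppressWarnings(stats::cor(nd, trait, use = "pairwise.complete.obs"))
      if (!is.finite(r)) r <- 0
      out[i, j] <- out[j, i] <- r^2
    }
  }
  out
}

rotate_z <- function(pts, theta) {
  r <- matrix(
    c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
    3, 3,
    byrow = TRUE
  )
  pts %*% t(r)
}
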