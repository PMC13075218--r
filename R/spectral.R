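#' Savitzky-Golay smoothing of spectra
#'
#' Applies least-squares local polynomial (Savitzky-Golay) convolution along
#' the band axis of each spectrum. Window ends are handled by polynomial fits
#' on the terminal windows, so any polynomial of degree `<= polyorder` passes
#' through unchanged (constants trivially so). Metadata columns are preserved.
#'
#' @param spectra A wide spectra tibble (see [reflectance_matrix()]).
#' @param window Odd window length in bands, `polyorder < window <= n_bands`.
#' @param polyorder Polynomial order, `>= 0`.
#'
#' @return The input tibble with the band columns smoothed.
#' @export
#'
#' @examples
#' sim <- simulate_planted_pair(6, 560, 690, seed = 1)
#' smooth <- sg_smooth(sim$spectra)
sg_smooth <- function(spectra, window = 11, polyorder = 2) {
  assert_scalar_number(window, "window", lower = 1)
  assert_scalar_number(polyorder, "polyorder", lower = 0)
  if (window %% 2 == 0) stop_input("`window` must be odd.")
  if (polyorder >= window) stop_input("`polyorder` must be < `window`.")
  cols <- spectra_band_cols(spectra)
  if (length(cols) == 0) stop_input("no reflectance band columns found.")
  if (window > length(cols)) stop_input("`window` exceeds the number of bands.")
  m <- reflectance_matrix(spectra)
  sm <- t(apply(m, 1, signal::sgolayfilt, p = polyorder, n = window))
  out <- spectra
  out[, cols] <- tibble::as_tibble(sm, .name_repair = ~cols)
  out
}

#' Normalized difference spectral index
#'
#' `NDSI(i, j) = (R_i - R_j) / (R_i + R_j)` for reflectances at the two
#' wavelengths, mapped to the nearest grid bands. Antisymmetric under band
#' swap; values lie in `[-1, 1]`. A zero reflectance sum yields `NA` with a
#' warning rather than a number.
#'
#' @param spectra A wide spectra tibble.
#' @param lambda_i,lambda_j Wavelengths in nm within the grid range.
#'
#' @return A numeric vector, one NDSI value per spectrum row.
#' @export
ndsi <- function(spectra, lambda_i, lambda_j) {
  m <- reflectance_matrix(spectra)
  wl <- spectra_wavelengths(spectra)
  idx <- band_index(c(lambda_i, lambda_j), grid = wl)
  ri <- m[, idx[1]]
  rj <- m[, idx[2]]
  denom <- ri + rj
  bad <- denom == 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "NDSI undefined (zero reflectance sum) for %d sample(s); returning NA.",
      sum(bad)
    ))
    denom[bad] <- NA_real_
  }
  unname((ri - rj) / denom)
}

#' Full-spectrum NDSI band-pair screen
#'
#' Step 1 of the two-step feature screen: for every band pair `(i, j)` the
#' association between the per-sample NDSI values and the trait is scored
#' across the whole 400-1000 nm grid, producing the score map whose maximum
#' identifies the optimal pair. The default statistic is the squared Pearson
#' correlation (R2) of the linear NDSI-trait fit; Spearman's rank correlation
#' (squared) is available for consistency with rank-based reporting.
#'
#' @param spectra A wide spectra tibble (all on one grid; `>= 3` rows).
#' @param trait Numeric trait vector, one value per spectrum row.
#' @param stride Evaluate every `stride`-th band (for speed); evaluated pairs
#'   score identically to a full screen.
#' @param stat `"r2"` (default) or `"spearman"`.
#' @param trait_label Optional label stored with the result.
#'
#' @return An object of class `canopyn_score_matrix`: a list with `scores`
#'   (B x B symmetric matrix, zero diagonal and at unevaluated strided pairs),
#'   `wavelengths`, `stat`, `stride`, `trait_label`, plus `stage`/`altitude`
#'   if those columns are constant in `spectra`.
#' @export
band_pair_screen <- function(spectra, trait, stride = 1,
                             stat = c("r2", "spearman"),
                             trait_label = deparse(substitute(trait))) {
  stat <- match.arg(stat)
  m <- reflectance_matrix(spectra)
  if (nrow(m) < 3) stop_input("need at least 3 spectra.")
  if (length(trait) != nrow(m)) {
    stop_input("`trait` length must equal the number of spectra.")
  }
  if (any(!is.finite(trait))) stop_input("`trait` must be finite.")
  if (stats::sd(trait) == 0) stop_input("`trait` has zero variance.")
  assert_scalar_number(stride, "stride", lower = 1)
  wl <- spectra_wavelengths(spectra)
  b <- length(wl)
  idx <- seq(1, b, by = as.integer(stride))

  method <- if (stat == "spearman") "spearman" else "pearson"
  scores <- matrix(0, b, b)
  n_degenerate <- 0
  for (i in idx) {
    ri <- m[, i]
    nmat <- (ri - m[, idx, drop = FALSE]) / (ri + m[, idx, drop = FALSE])
    nmat[!is.finite(nmat)] <- NA_real_ # zero reflectance sums
    r <- suppressWarnings(as.numeric(
      stats::cor(nmat, trait, use = "pairwise.complete.obs", method = method)
    ))
    degenerate <- !is.finite(r)
    n_degenerate <- n_degenerate + sum(degenerate & idx != i)
    r[degenerate] <- 0
    scores[i, idx] <- r^2
  }
  diag(scores) <- 0
  scores <- pmax(scores, t(scores)) # exact mirror of the evaluated triangle
  if (n_degenerate > 0) {
    rlang::warn(sprintf(
      "%d band pair(s) had zero-variance NDSI; scored 0.", n_degenerate / 2
    ))
  }
  meta <- list()
  for (col in c("stage", "altitude")) {
    if (col %in% names(spectra) && length(unique(spectra[[col]])) == 1) {
      meta[[col]] <- spectra[[col]][1]
    }
  }
  structure(
    list(
      scores = scores, wavelengths = wl, stat = stat,
      stride = as.integer(stride), trait_label = trait_label,
      stage = meta$stage, altitude = meta$altitude
    ),
    class = "canopyn_score_matrix"
  )
}

#' @export
print.canopyn_score_matrix <- function(x, ...) {
  cat(sprintf(
    "NDSI band-pair screen (%s) on %d bands; max score %.3f\n",
    x$stat, length(x$wavelengths), max(x$scores)
  ))
  invisible(x)
}

#' Select the best band pair from a score matrix
#'
#' Returns the maximizing pair `(lambda_i < lambda_j)`; ties are broken by the
#' smallest `lambda_i`, then the smallest `lambda_j`. Wavelengths are also
#' reported rounded to integer nm, the conventional way such pairs are cited.
#'
#' @param score_matrix A `canopyn_score_matrix` from [band_pair_screen()].
#'
#' @return A one-row tibble: `lambda_i`, `lambda_j` (exact grid nm),
#'   `lambda_i_nm`, `lambda_j_nm` (rounded integers), `band_i`, `band_j`,
#'   `score`, `stat`, `trait_label`, `stage`, `altitude`.
#' @export
select_best_pair <- function(score_matrix) {
  if (!inherits(score_matrix, "canopyn_score_matrix")) {
    stop_input("`score_matrix` must come from band_pair_screen().")
  }
  s <- score_matrix$scores
  s[lower.tri(s, diag = TRUE)] <- -Inf
  best <- max(s)
  if (!is.finite(best) || best <= 0) {
    stop_input("score matrix carries no signal (all entries zero).",
      class = "canopyn_no_signal"
    )
  }
  hits <- which(s == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]
  j <- hits[1, 2]
  wl <- score_matrix$wavelengths
  tibble::tibble(
    lambda_i = wl[i], lambda_j = wl[j],
    lambda_i_nm = round(wl[i]), lambda_j_nm = round(wl[j]),
    band_i = i, band_j = j, score = best,
    stat = score_matrix$stat,
    trait_label = score_matrix$trait_label %||% NA_character_,
    stage = score_matrix$stage %||% NA,
    altitude = score_matrix$altitude %||% NA
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the headline association
#' statistic for reporting trait-feature relationships.
#'
#' @param x,y Equal-length numeric vectors (length `>= 3`).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
#'
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5)) # 0.8
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_input("`x` and `y` must have equal length >= 3.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_input("inputs must be finite.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("zero-variance input.")
  }
  stats::cor(x, y, method = "spearman")
}
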