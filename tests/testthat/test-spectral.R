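test_that("wavelength grid and band mapping follow the sensor layout", {
  wl <- wavelength_grid()
  expect_length(wl, 561)
  expect_equal(wl[1], 400)
  expect_equal(wl[2] - wl[1], 1.07)
  expect_lt(max(wl), 1000)
  expect_equal(band_index(400), 1L)
  expect_equal(band_index(999.2), 561L)
  expect_equal(band_index(560.5), which.min(abs(wl - 560.5)))
  expect_error(band_index(1200), "outside")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials exactly", {
  wl <- wavelength_grid()
  const <- toy_spectra(matrix(0.3, 2, 561), wl)
  out <- sg_smooth(const, window = 11, polyorder = 2)
  expect_equal(reflectance_matrix(out), reflectance_matrix(const), tolerance = 1e-12)

  # a cubic passes through an order-3 filter unchanged (edges included)
  x <- (wl - 700) / 300
  cubic <- 0.2 + 0.1 * x + 0.05 * x^2 - 0.04 * x^3
  sp <- toy_spectra(rbind(cubic), wl)
  sm <- sg_smooth(sp, window = 11, polyorder = 3)
  expect_lt(max(abs(reflectance_matrix(sm) - rbind(cubic))), 1e-10)

  # white noise: smoothing is variance-contractive
  set.seed(42)
  noise <- matrix(rnorm(5 * 561, 0.5, 0.02), 5)
  nsp <- toy_spectra(noise, wl)
  nsm <- sg_smooth(nsp, window = 11, polyorder = 2)
  expect_lt(
    mean(apply(reflectance_matrix(nsm), 1, var)),
    mean(apply(noise, 1, var))
  )
  # metadata and shape preserved
  nsp$stage <- "VGS"
  out2 <- sg_smooth(nsp)
  expect_equal(out2$stage, nsp$stage)
  expect_equal(dim(out2), dim(nsp))

  expect_error(sg_smooth(nsp, window = 10), "odd")
  expect_error(sg_smooth(nsp, window = 5, polyorder = 5), "polyorder")
})

test_that("NDSI is the normalized difference with its symmetries", {
  wl <- c(500, 600, 700)
  sp <- toy_spectra(rbind(c(0.5, 0.5, 0.1), c(0.3, 0.1, 0.2)), wl)
  expect_equal(ndsi(sp, 500, 600), c(0, 0.5))
  expect_equal(ndsi(sp, 500, 700), -ndsi(sp, 700, 500))
  set.seed(1)
  rnd <- toy_spectra(matrix(runif(100 * 3, 0.05, 0.9), 100), wl)
  expect_equal(ndsi(rnd, 500, 700), -ndsi(rnd, 700, 500), tolerance = 1e-14)
  zero <- toy_spectra(rbind(c(0, 0.5, 0.2)), wl)
  expect_warning(v <- ndsi(zero, 500, 500), "undefined")
  expect_true(is.na(v))
})

test_that("band-pair screen matches a brute-force oracle and finds planted pairs", {
  # 3-band construction: trait = 2 * NDSI(band1, band3) exactly
  wl <- c(450, 550, 650)
  set.seed(3)
  m <- matrix(runif(15, 0.1, 0.8), 5, 3)
  sp <- toy_spectra(m, wl)
  trait <- 2 * (m[, 1] - m[, 3]) / (m[, 1] + m[, 3])
  scr <- band_pair_screen(sp, trait)
  expect_equal(scr$scores[1, 3], 1.0, tolerance = 1e-12)
  best <- select_best_pair(scr)
  expect_equal(c(best$lambda_i, best$lambda_j), c(450, 650))

  # entrywise equality with the independent double loop on a 25-band instance
  set.seed(4)
  wl25 <- seq(400, 1000, length.out = 25)
  m25 <- matrix(runif(12 * 25, 0.05, 0.9), 12)
  t25 <- rnorm(12)
  sp25 <- toy_spectra(m25, wl25)
  expect_lt(
    max(abs(band_pair_screen(sp25, t25)$scores - brute_force_screen(sp25, t25))),
    1e-12
  )
  # symmetry and stride consistency
  scr25 <- band_pair_screen(sp25, t25)
  expect_equal(scr25$scores, t(scr25$scores))
  scr_str <- band_pair_screen(sp25, t25, stride = 3)
  idx <- seq(1, 25, by = 3)
  expect_equal(scr_str$scores[idx, idx], scr25$scores[idx, idx], tolerance = 1e-14)

  # shuffled trait carries no signal
  sim <- simulate_planted_pair(200, 550, 750, seed = 5)
  maxima <- vapply(1:10, function(s) {
    shuffled <- with(list(), {
      set.seed(s)
      sample(sim$trait)
    })
    max(band_pair_screen(sim$spectra, shuffled)$scores)
  }, numeric(1))
  expect_lt(median(maxima), 0.15)

  expect_error(band_pair_screen(sp, rep(1, 5)), "variance")
  expect_error(band_pair_screen(sp, trait[1:3]), "length")
})

test_that("best-pair selection reports the maximum with deterministic ties", {
  wl <- wavelength_grid()
  s <- matrix(0, 561, 561)
  i <- band_index(560)
  j <- band_index(690)
  s[i, j] <- s[j, i] <- 0.93
  s[band_index(450), band_index(800)] <- s[band_index(800), band_index(450)] <- 0.5
  scr <- structure(
    list(
      scores = s, wavelengths = wl, stat = "r2", stride = 1L,
      trait_label = "cnc", stage = NULL, altitude = NULL
    ),
    class = "canopyn_score_matrix"
  )
  best <- select_best_pair(scr)
  expect_equal(c(best$lambda_i_nm, best$lambda_j_nm), c(560, 690))
  expect_equal(best$score, 0.93)

  # tie: lexicographically smallest pair wins
  s2 <- s
  s2[band_index(600), band_index(900)] <- s2[band_index(900), band_index(600)] <- 0.93
  scr$scores <- s2
  best2 <- select_best_pair(scr)
  expect_equal(c(best2$lambda_i_nm, best2$lambda_j_nm), c(560, 690))

  scr$scores <- matrix(0, 561, 561)
  expect_error(select_best_pair(scr), class = "canopyn_no_signal")
})

test_that("spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_cor(1:10, (1:10)^3), 1.0)
  expect_equal(spearman_cor(1:10, rev(1:10)), -1.0)
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_cor(1:5, rep(2, 5)), "variance")
  expect_error(spearman_cor(1:2, 1:2), "length")
})
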