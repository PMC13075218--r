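test_that("ground-truth tables are deterministic and internally consistent", {
  gt1 <- generate_ground_truth(experiment_design(), seed = 7)
  gt2 <- generate_ground_truth(experiment_design(), seed = 7)
  expect_identical(gt1, gt2)
  gt3 <- generate_ground_truth(experiment_design(), seed = 8)
  expect_false(identical(gt1$biomass, gt3$biomass))

  # every record satisfies the defining identities to machine precision
  expect_equal(gt1$cnc, gt1$nc_leaf, tolerance = 1e-12)
  agna_direct <- gt1$nc_leaf * gt1$m_leaf + gt1$nc_shoot * gt1$m_shoot +
    gt1$nc_fruit * gt1$m_fruit + gt1$nc_trunk * gt1$m_trunk
  expect_equal(gt1$agna, agna_direct, tolerance = 1e-12)
  expect_equal(gt1$biomass, gt1$m_leaf + gt1$m_shoot + gt1$m_fruit + gt1$m_trunk,
    tolerance = 1e-12
  )
  expect_true(all(gt1$m_fruit[gt1$stage == "VGS"] == 0))
  expect_true(all(gt1$m_fruit[gt1$stage == "FES"] > 0))
  expect_true(all(as.matrix(gt1[, grep("^(m|nc)_", names(gt1))]) >= 0))

  # default design: 4 rates x 3 reps x 4 trees = 48 trees per site x stage
  counts <- dplyr::count(gt1, site, stage)
  expect_true(all(counts$n == 48))
})

test_that("effect profiles change the dose-response structure", {
  d <- experiment_design(sites = "Lishi", stages = "VGS")
  flat <- generate_ground_truth(d, "flat_null", seed = 1)
  cal <- generate_ground_truth(d, "table1_calibrated", seed = 1)
  # calibrated biomass increases with rate at VGS; flat does not systematically
  mean_by_rate <- function(gt) {
    tapply(gt$biomass, gt$rate_label, mean)
  }
  expect_true(all(diff(mean_by_rate(cal)) > -0.1))
  expect_gt(mean_by_rate(cal)[["N3"]], mean_by_rate(cal)[["N0"]] + 0.5)
  expect_lt(abs(mean_by_rate(flat)[["N3"]] - mean_by_rate(flat)[["N0"]]), 0.8)
  # CNC effects small at VGS, large (peak N2) at FES, per the calibration table
  ref <- nitrogen_reference_summary()
  cnc_fes <- ref[ref$variable == "cnc" & ref$stage == "FES" & ref$site == "Ciyun", ]
  expect_equal(cnc_fes$rate_label[which.max(cnc_fes$mean)], "N2")
  expect_error(
    generate_ground_truth(d, "no_such_profile", seed = 1),
    "arg"
  )
  expect_error(experiment_design(replicates = 0), "replicates")
  expect_error(experiment_design(n_rates = c(100, 50)), "increasing")
})

test_that("canopy spectra respond to nitrogen, density and altitude as built", {
  sc0 <- scene_params(60, noise_sd = 0, soil_fraction = 0)
  s1 <- generate_canopy_spectrum(25, 0.7, sc0, seed = 1)
  s1b <- generate_canopy_spectrum(25, 0.7, sc0, seed = 99)
  expect_identical(s1$reflectance, s1b$reflectance) # noise-free => deterministic
  expect_true(all(s1$reflectance >= 0 & s1$reflectance <= 1))
  expect_equal(nrow(s1), 561)

  # reflectance in the red absorption well strictly decreases as cnc doubles
  r670 <- function(cnc) {
    sp <- generate_canopy_spectrum(cnc, 0.7, sc0, seed = 1)
    sp$reflectance[which.min(abs(sp$wavelength - 670))]
  }
  expect_lt(r670(40), r670(20))
  expect_lt(r670(20), r670(10))

  # monotone sweeps: 670 nm non-increasing in cnc; NIR non-decreasing in density
  wells <- vapply(seq(5, 45, by = 5), r670, numeric(1))
  expect_true(all(diff(wells) <= 1e-12))
  nir <- vapply(seq(0.1, 1, by = 0.1), function(d) {
    sp <- generate_canopy_spectrum(30, d, sc0, seed = 1)
    mean(sp$reflectance[sp$wavelength > 800])
  }, numeric(1))
  expect_true(all(diff(nir) >= -1e-12))

  # higher flight altitude mixes in more soil: visible up, NIR down
  s60 <- generate_canopy_spectrum(33, 0.7, scene_params(60), seed = 2)
  s100 <- generate_canopy_spectrum(33, 0.7, scene_params(100), seed = 2)
  band_mean <- function(sp, lo, hi) {
    mean(sp$reflectance[sp$wavelength >= lo & sp$wavelength <= hi])
  }
  expect_gt(band_mean(s100, 500, 550), band_mean(s60, 500, 550))
  expect_lt(band_mean(s100, 800, 1000), band_mean(s60, 800, 1000))

  expect_error(generate_canopy_spectrum(-1, 0.5), "cnc")
  expect_error(generate_canopy_spectrum(30, 0), "canopy_density")
  expect_error(scene_params(70), "not allowed")
})

test_that("tree point clouds honour the stated geometry", {
  cl <- generate_tree_point_cloud(3, 2, 1.5, jitter_sd = 0, seed = 1)
  expect_equal(max(cl$z), 3.0) # deterministic apex point
  expect_setequal(unique(cl$part), c("ground", "trunk", "crown"))
  crown <- cl[cl$part == "crown", ]
  expect_true(all(crown$z >= 1.5 - 1e-9))
  expect_true(all(crown$x^2 + crown$y^2 <= 1 + 1e-9))

  # dense crown: hull volume close to the analytic ellipsoid volume
  dense <- generate_tree_point_cloud(3, 2, 1.5,
    point_density = 4000, ground_density = 0, trunk_points = 0, seed = 2
  )
  v <- convex_hull_volume(dense[dense$part == "crown", c("x", "y", "z")])
  expect_lt(abs(v - 4 / 3 * pi * 1 * 1 * 0.75) / (4 / 3 * pi * 0.75), 0.05)

  # empty crown propagates to the documented degenerate-geometry error
  bare <- generate_tree_point_cloud(3, 2, 1.5,
    point_density = 0, ground_density = 5, trunk_points = 0, seed = 1
  )
  expect_error(tree_metrics(bare, "bare"), class = "canopyn_degenerate_geometry")

  expect_error(generate_tree_point_cloud(2, 1, 2.5), "crown_depth")
  expect_error(generate_tree_point_cloud(-1, 1, 0.5), "ph")
})

test_that("dataset bundles are complete and round-trip through disk", {
  design <- experiment_design(
    sites = "Lishi", stages = "FES", replicates = 2, trees_per_cell = 1
  )
  bundle <- generate_dataset(design,
    scenes = default_scenes(c(60, 100)), seed = 3,
    cloud_args = list(point_density = 60, ground_density = 5)
  )
  n <- nrow(bundle$ground_truth)
  expect_equal(n, 4 * 2)
  expect_named(bundle$spectra, c("60", "100"))
  expect_equal(nrow(bundle$spectra[["60"]]), n) # one spectrum per tree per altitude
  expect_length(bundle$clouds, n)

  dir <- withr::local_tempdir()
  write_dataset(bundle, dir)
  back <- read_dataset(dir)
  expect_equal(back$ground_truth, bundle$ground_truth, tolerance = 1e-9)
  expect_equal(
    reflectance_matrix(back$spectra[["60"]]),
    reflectance_matrix(bundle$spectra[["60"]]),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  id <- bundle$ground_truth$tree_id[1]
  expect_equal(
    as.matrix(back$clouds[[id]]),
    as.matrix(bundle$clouds[[id]][, c("x", "y", "z")]),
    tolerance = 1e-5, ignore_attr = TRUE
  )

  # same seed: identical bundle; different seed: same skeleton, different noise
  b2 <- generate_dataset(design,
    scenes = default_scenes(c(60, 100)), seed = 3,
    cloud_args = list(point_density = 60, ground_density = 5)
  )
  expect_equal(bundle$ground_truth, b2$ground_truth)
  b3 <- generate_dataset(design,
    scenes = default_scenes(c(60, 100)), seed = 4,
    cloud_args = list(point_density = 60, ground_density = 5)
  )
  expect_identical(b3$ground_truth$tree_id, bundle$ground_truth$tree_id)
  expect_false(identical(
    reflectance_matrix(b3$spectra[["60"]]),
    reflectance_matrix(bundle$spectra[["60"]])
  ))
})

test_that("study-style subsampling picks the right number of trees per cell", {
  gt <- generate_ground_truth(seed = 2)
  sub <- sample_study_trees(gt, per_cell = 2, seed = 1)
  counts <- dplyr::count(sub, site, stage, rate_label)
  expect_true(all(counts$n == 2))
  expect_equal(nrow(dplyr::filter(sub, stage == "FES")), 16)
})
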